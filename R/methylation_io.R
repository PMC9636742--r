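# Reading, writing and assembling per-CpG bisulfite methylation counts.
#
# One internal convention everywhere: a methylation call table is a data.frame
# with columns chrom (character), pos (0-based integer position of the
# cytosine), strand ("+", "-" or "."), meth and unmeth (non-negative integer
# read counts). File-format conversions happen on ingest only:
# bismark-coverage is 1-based inclusive, bedGraph is 0-based half-open.

#' Read per-CpG methylation calls for one sample
#'
#' Parses a per-sample methylation call file into a site table of raw
#' methylated/unmethylated read counts.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`bismark_cov`}{6 tab-separated columns: chrom, start (1-based),
#'     end, methylation percentage, count methylated, count unmethylated.
#'     The percentage column is ignored in favour of the raw counts; if it
#'     disagrees with the counts by more than 0.5 percentage points a warning
#'     is emitted and the counts win.}
#'   \item{`bedgraph`}{4 columns: chrom, start (0-based), end, methylation
#'     fraction. Fractions alone carry no read-level evidence, so a companion
#'     counts file (`counts_path`, tab-separated chrom, start (0-based), end,
#'     count methylated, count unmethylated) is required; without it the file
#'     is rejected for calling.}
#' }
#'
#' Rows with zero coverage are retained: missing evidence is represented as
#' coverage 0, never imputed.
#'
#' @param path Path to the call file.
#' @param dialect `"bismark_cov"` (default) or `"bedgraph"`.
#' @param counts_path Companion counts file, required for the bedGraph dialect.
#' @param strand Strand symbol to assign to all sites (these file formats do
#'   not carry strand). One of `"+"`, `"-"`, `"."`; default `"."`.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth`, `unmeth`.
#' @seealso [build_matrix()], [write_methylation_calls()]
#' @export
read_methylation_calls <- function(path,
                                   dialect = c("bismark_cov", "bedgraph"),
                                   counts_path = NULL,
                                   strand = ".") {
  dialect <- match.arg(dialect)
  stopifnot(strand %in% c("+", "-", "."))
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)

  lines <- readLines(path)
  lines <- lines[!grepl("^track|^#", lines)]
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), stringsAsFactors = FALSE)
  if (dialect == "bismark_cov") {
    if (length(lines) == 0) return(empty)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncol_ok <- lengths(parts) == 6L
    if (any(!ncol_ok))
      stop_parse(path, which(!ncol_ok)[1], "expected 6 tab-separated columns")
    m <- do.call(rbind, parts)
    for (j in c(5L, 6L)) {
      bad <- !is_count(m[, j])
      if (any(bad))
        stop_parse(path, which(bad)[1],
                   sprintf("column %d must be a non-negative integer count", j))
    }
    meth <- as.integer(m[, 5]); unmeth <- as.integer(m[, 6])
    pct <- suppressWarnings(as.numeric(m[, 4]))
    cov <- meth + unmeth
    have <- !is.na(pct) & cov > 0
    off <- abs(pct[have] - 100 * meth[have] / cov[have])
    if (any(off > 0.5))
      warning(sprintf(
        "%d row(s) in '%s' have a methylation %% inconsistent with counts by > 0.5; counts win",
        sum(off > 0.5), path), call. = FALSE)
    out <- data.frame(chrom = m[, 1], pos = to0based(m[, 2]), strand = strand,
                      meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
  } else {
    if (is.null(counts_path))
      stop("bedGraph dialect carries fractions only and is rejected for calling ",
           "without a companion counts file (counts_path)", call. = FALSE)
    if (!file.exists(counts_path))
      stop(sprintf("file not found: '%s'", counts_path), call. = FALSE)
    clines <- readLines(counts_path)
    clines <- clines[!grepl("^track|^#", clines)]
    if (length(clines) == 0) return(empty)
    parts <- strsplit(clines, "\t", fixed = TRUE)
    ncol_ok <- lengths(parts) == 5L
    if (any(!ncol_ok))
      stop_parse(counts_path, which(!ncol_ok)[1], "expected 5 tab-separated columns")
    m <- do.call(rbind, parts)
    for (j in c(4L, 5L)) {
      bad <- !is_count(m[, j])
      if (any(bad))
        stop_parse(counts_path, which(bad)[1],
                   sprintf("column %d must be a non-negative integer count", j))
    }
    meth <- as.integer(m[, 4]); unmeth <- as.integer(m[, 5])
    out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), strand = strand,
                      meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
    # Cross-check the fraction track against the counts where both exist.
    if (length(lines) > 0) {
      fparts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(fparts) < 4L))
        stop_parse(path, which(lengths(fparts) < 4L)[1],
                   "expected >= 4 tab-separated columns")
      fm <- do.call(rbind, lapply(fparts, `[`, 1:4))
      key_f <- paste(fm[, 1], fm[, 2]); key_c <- paste(out$chrom, out$pos)
      i <- match(key_c, key_f)
      frac <- suppressWarnings(as.numeric(fm[i, 4]))
      cov <- meth + unmeth
      have <- !is.na(frac) & cov > 0
      off <- abs(frac[have] - meth[have] / cov[have])
      if (any(off > 0.005))
        warning(sprintf(
          "%d site(s) in '%s' have a fraction inconsistent with counts by > 0.5%%; counts win",
          sum(off > 0.005), path), call. = FALSE)
    }
  }
  if (any(out$pos < 0)) stop_parse(path, which(out$pos < 0)[1], "negative position")
  out
}

#' Write per-CpG methylation calls
#'
#' Inverse of [read_methylation_calls()]; used for round-trip testing and for
#' emitting intermediate artifacts. The bedGraph dialect writes the fraction
#' track to `path` and the companion counts file to `counts_path`.
#'
#' @param calls Site table as returned by [read_methylation_calls()].
#' @param path Output path.
#' @param dialect `"bismark_cov"` or `"bedgraph"`.
#' @param counts_path Companion counts path (bedGraph dialect only).
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path,
                                    dialect = c("bismark_cov", "bedgraph"),
                                    counts_path = NULL) {
  dialect <- match.arg(dialect)
  cov <- calls$meth + calls$unmeth
  frac <- ifelse(cov > 0, calls$meth / cov, 0)
  if (dialect == "bismark_cov") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                     calls$chrom, to1based(calls$pos), to1based(calls$pos),
                     formatC(100 * frac, format = "f", digits = 6),
                     calls$meth, calls$unmeth)
    writeLines(lines, path)
  } else {
    if (is.null(counts_path))
      stop("bedgraph dialect needs counts_path", call. = FALSE)
    writeLines(sprintf("%s\t%d\t%d\t%s", calls$chrom, calls$pos,
                       calls$pos + 1L,
                       formatC(frac, format = "f", digits = 6)), path)
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d", calls$chrom, calls$pos,
                       calls$pos + 1L, calls$meth, calls$unmeth), counts_path)
  }
  invisible(path)
}

#' Assemble per-sample call tables into a methylation matrix
#'
#' Takes one call table per sample plus a sample-to-group mapping and builds a
#' `MethylationMatrix`: the union of all sites (sorted by chromosome then
#' position), with methylated and unmethylated counts as site-by-sample
#' matrices. A (site, sample) pair absent from that sample's file gets
#' coverage 0.
#'
#' CpG sites reported on opposite strands are kept separate by default; with
#' `merge_strands = TRUE` minus-strand calls are destranded onto the
#' plus-strand cytosine (position - 1) and counts are summed.
#'
#' @param tables Named list of per-sample call tables
#'   (see [read_methylation_calls()]); names are sample ids.
#' @param groups Named character vector mapping every sample id to `"case"` or
#'   `"control"`.
#' @param merge_strands Destrand CpGs onto the plus-strand cytosine.
#' @return An object of class `MethylationMatrix`: a list with `sites`
#'   (data.frame chrom/pos/strand), `samples`, `group`, and integer matrices
#'   `meth` and `unmeth` (sites x samples).
#' @export
build_matrix <- function(tables, groups, merge_strands = FALSE) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list (sample ids)", call. = FALSE)
  samples <- names(tables)
  missing_grp <- setdiff(samples, names(groups))
  if (length(missing_grp) > 0)
    stop(sprintf("sample(s) without group label: %s",
                 paste(missing_grp, collapse = ", ")), call. = FALSE)
  groups <- groups[samples]
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (sum(groups == "case") < 1 || sum(groups == "control") < 1)
    stop("need at least one case and one control sample", call. = FALSE)

  tables <- lapply(tables, function(tb) {
    if (merge_strands) {
      neg <- tb$strand == "-"
      tb$pos[neg] <- tb$pos[neg] - 1L
      tb$strand[neg] <- "+"
      if (anyDuplicated(tb[c("chrom", "pos", "strand")])) {
        tb <- stats::aggregate(cbind(meth, unmeth) ~ chrom + pos + strand,
                               data = tb, FUN = sum)
      }
    }
    tb
  })

  for (s in samples) {
    dup <- duplicated(tables[[s]][c("chrom", "pos", "strand")])
    if (any(dup))
      stop(sprintf("duplicate site %s:%d(%s) in sample '%s'",
                   tables[[s]]$chrom[dup][1], tables[[s]]$pos[dup][1],
                   tables[[s]]$strand[dup][1], s), call. = FALSE)
  }

  all_sites <- unique(do.call(rbind, lapply(tables, function(tb)
    tb[c("chrom", "pos", "strand")])))
  ord <- order(all_sites$chrom, all_sites$pos, all_sites$strand)
  sites <- all_sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos, sites$strand)

  n <- nrow(sites)
  meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  unmeth <- meth
  for (s in samples) {
    tb <- tables[[s]]
    i <- match(paste(tb$chrom, tb$pos, tb$strand), key)
    meth[i, s] <- as.integer(tb$meth)
    unmeth[i, s] <- as.integer(tb$unmeth)
  }
  structure(list(sites = sites, samples = samples, group = groups,
                 meth = meth, unmeth = unmeth),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d sites x %d samples (%d case, %d control)\n",
              nrow(x$sites), length(x$samples),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

# Subset a MethylationMatrix to a logical/integer site index.
subset_sites <- function(mat, idx) {
  structure(list(sites = mat$sites[idx, , drop = FALSE],
                 samples = mat$samples, group = mat$group,
                 meth = mat$meth[idx, , drop = FALSE],
                 unmeth = mat$unmeth[idx, , drop = FALSE]),
            class = "MethylationMatrix")
}

#' Coverage-filter a methylation matrix
#'
#' Retains sites where at least `min_fraction_samples` of the samples in
#' \emph{each} group have coverage (methylated + unmethylated) of at least
#' `min_cov`. Idempotent and monotone: raising `min_cov` never adds sites.
#'
#' @param mat A `MethylationMatrix`.
#' @param min_cov Minimum per-sample coverage (>= 1).
#' @param min_fraction_samples Fraction of samples per group that must reach
#'   `min_cov`, in (0, 1].
#' @return A filtered `MethylationMatrix`.
#' @export
filter_by_coverage <- function(mat, min_cov = 10L, min_fraction_samples = 0.75) {
  stopifnot(inherits(mat, "MethylationMatrix"),
            min_cov >= 1, min_fraction_samples > 0, min_fraction_samples <= 1)
  cov <- mat$meth + mat$unmeth
  keep <- rep(TRUE, nrow(mat$sites))
  for (g in c("case", "control")) {
    cols <- mat$samples[mat$group == g]
    frac <- rowMeans(cov[, cols, drop = FALSE] >= min_cov)
    keep <- keep & (frac >= min_fraction_samples)
  }
  subset_sites(mat, keep)
}
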