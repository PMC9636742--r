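# Differential single-CpG epimutation calling.
#
# Statistic: counts are pooled within each group and compared with a two-sided
# Fisher exact test on the 2x2 table [meth_case, unmeth_case; meth_control,
# unmeth_control]; the effect size is the coverage-weighted pooled fraction
# difference. Fisher is exact at the low per-site coverages bisulfite capture
# yields, and ranking by |delta| mirrors selection of the sites with the
# highest differential methylation rates.

# Two-sided Fisher exact p-values for the whole support of a 2x2 table with
# fixed margins: row sums r1, r2 and first-column sum c1. Returns a list with
# the support x (first-cell values) and p (two-sided p for each x). The
# two-sided p at x is the sum of hypergeometric probabilities of all tables
# at most as probable as x (with a small relative tolerance for ties, as in
# stats::fisher.test).
fisher_support <- function(r1, r2, c1) {
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  d <- stats::dhyper(x, m = r1, n = r2, k = c1)
  rel <- 1 + 1e-7
  p <- vapply(d, function(dx) sum(d[d <= dx * rel]), numeric(1))
  list(x = x, p = pmin(p, 1))
}

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Conditional hypergeometric tail-sum p-value for the table
#' `[a, b; c, d]`, defined (as in [stats::fisher.test()]) as the sum of
#' probabilities of all tables with the same margins that are at most as
#' probable as the observed one. Vectorised over the four cells.
#'
#' @param a,b,c,d Non-negative integer cell counts (rows: group 1, group 2;
#'   columns: methylated, unmethylated).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  rel <- 1 + 1e-7
  mapply(function(a, b, c, d) {
    if (a + b + c + d == 0) return(1)
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    x <- max(0L, c1 - r2):min(r1, c1)
    dd <- stats::dhyper(x, m = r1, n = r2, k = c1)
    min(1, sum(dd[dd <= dd[match(a, x)] * rel]))
  }, a, b, c, d)
}

#' Per-site differential methylation statistic
#'
#' Pools methylated/unmethylated counts across the samples of each group and
#' returns the coverage-weighted fraction difference together with the
#' two-sided Fisher exact p-value of the pooled 2x2 table.
#'
#' @param case,control Data frames (or lists) with numeric elements
#'   `methylated` and `unmethylated`, one entry per sample.
#' @return A list with `delta` (case minus control pooled methylation
#'   fraction, in \[-1, 1\]), `p_value`, `mean_case`, `mean_control`.
#' @export
site_statistic <- function(case, control) {
  mc <- sum(case$methylated);    uc <- sum(case$unmethylated)
  mk <- sum(control$methylated); uk <- sum(control$unmethylated)
  if (mc + uc == 0 || mk + uk == 0)
    stop("undefined statistic: zero total coverage in a group", call. = FALSE)
  mean_case <- mc / (mc + uc)
  mean_control <- mk / (mk + uk)
  list(delta = mean_case - mean_control,
       p_value = fisher_exact_2x2(mc, uc, mk, uk),
       mean_case = mean_case, mean_control = mean_control)
}

#' Call differential single-CpG epimutations
#'
#' Applies [site_statistic()] to every site of a (coverage-filtered)
#' methylation matrix, adjusts p-values across all tested sites with
#' Benjamini-Hochberg, and keeps sites with `|delta| >= min_abs_delta` and
#' `q_value <= alpha`. Calls are sorted by `|delta|` descending, ties broken
#' by smaller p-value, then by (chrom, pos), and assigned 1-based ranks.
#' The output is a deterministic function of the matrix and parameters.
#'
#' Sites with zero pooled coverage in either group cannot be tested and are
#' excluded from testing (and hence from the BH family).
#'
#' @param mat A `MethylationMatrix`.
#' @param min_cov Per-sample coverage needed for a sample to count as
#'   "covered" in `n_case_covered`/`n_control_covered` (default 1).
#' @param min_abs_delta Minimum absolute pooled methylation difference.
#' @param alpha FDR threshold on BH-adjusted p-values.
#' @return A data.frame of calls: `chrom`, `pos`, `strand`, `mean_case`,
#'   `mean_control`, `delta`, `p_value`, `q_value`, `rank`,
#'   `n_case_covered`, `n_control_covered`.
#' @export
call_epimutations <- function(mat, min_cov = 1L, min_abs_delta = 0.2,
                              alpha = 0.05) {
  stopifnot(inherits(mat, "MethylationMatrix"))
  empty <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      mean_case = numeric(), mean_control = numeric(),
                      delta = numeric(), p_value = numeric(),
                      q_value = numeric(), rank = integer(),
                      n_case_covered = integer(), n_control_covered = integer(),
                      stringsAsFactors = FALSE)
  n <- nrow(mat$sites)
  if (n == 0) return(empty)

  cs <- mat$samples[mat$group == "case"]
  ks <- mat$samples[mat$group == "control"]
  mc <- rowSums(mat$meth[, cs, drop = FALSE])
  uc <- rowSums(mat$unmeth[, cs, drop = FALSE])
  mk <- rowSums(mat$meth[, ks, drop = FALSE])
  uk <- rowSums(mat$unmeth[, ks, drop = FALSE])
  testable <- (mc + uc > 0) & (mk + uk > 0)
  if (!any(testable)) return(empty)

  idx <- which(testable)
  p <- fisher_exact_2x2(mc[idx], uc[idx], mk[idx], uk[idx])
  q <- stats::p.adjust(p, method = "BH")
  mean_case <- mc[idx] / (mc + uc)[idx]
  mean_control <- mk[idx] / (mk + uk)[idx]
  delta <- mean_case - mean_control

  covm <- mat$meth + mat$unmeth
  ncc <- rowSums(covm[, cs, drop = FALSE] >= min_cov)
  nkc <- rowSums(covm[, ks, drop = FALSE] >= min_cov)

  out <- data.frame(chrom = mat$sites$chrom[idx], pos = mat$sites$pos[idx],
                    strand = mat$sites$strand[idx],
                    mean_case = mean_case, mean_control = mean_control,
                    delta = delta, p_value = p, q_value = q,
                    n_case_covered = as.integer(ncc[idx]),
                    n_control_covered = as.integer(nkc[idx]),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$delta) >= min_abs_delta & out$q_value <= alpha, ,
             drop = FALSE]
  if (nrow(out) == 0) { empty$rank <- integer(); return(empty[names(empty)]) }
  out <- out[order(-abs(out$delta), out$p_value, out$chrom, out$pos), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("chrom", "pos", "strand", "mean_case", "mean_control", "delta",
        "p_value", "q_value", "rank", "n_case_covered", "n_control_covered")]
}

#' Top-ranked epimutation calls
#'
#' First `min(k, nrow(calls))` calls by rank (the study design carries the two
#' best differential sites forward to lncRNA discovery, i.e. `k = 2`).
#'
#' @param calls Call table from [call_epimutations()].
#' @param k Number of calls to keep (>= 1).
#' @return The top `k` rows of `calls`.
#' @export
top_candidates <- function(calls, k = 2L) {
  stopifnot(k >= 1)
  calls[seq_len(min(k, nrow(calls))), , drop = FALSE]
}

#' Candidate MS-HRM primer regions around an epimutation
#'
#' Scans all windows that contain the anchor CpG with length in
#' `[min_len, max_len]`, counts CG dinucleotides on the plus strand inside
#' each window, and returns windows whose CpG count is in
#' `[min_cpgs, max_cpgs]`, sorted by CpG count descending then length
#' ascending. Window coordinates are 0-based half-open. Windows are clipped at
#' contig ends; an anchor too close to an end yields clipped windows or an
#' empty result, never an error.
#'
#' Defaults reflect typical methylation-sensitive high-resolution melting
#' (MS-HRM) amplicon design: short amplicons (80-150 bp) with a handful of
#' informative CpGs.
#'
#' @param call A single row of the call table from [call_epimutations()] (or
#'   any list with `chrom` and `pos`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param min_len,max_len Window length bounds in nt.
#' @param min_cpgs,max_cpgs Bounds on the number of CG dinucleotides inside a
#'   reported window.
#' @return Data frame with `chrom`, `start`, `end`, `length_nt`, `n_cpgs`,
#'   `anchor_pos`.
#' @export
find_primer_regions <- function(call, genome, min_len = 80L, max_len = 150L,
                                min_cpgs = 3L, max_cpgs = 10L) {
  chrom <- call$chrom[1]; pos <- as.integer(call$pos[1])
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' not present in genome", chrom), call. = FALSE)
  stopifnot(min_len >= 2, max_len >= min_len, min_cpgs >= 0,
            max_cpgs >= min_cpgs)
  clen <- Biostrings::width(genome[chrom])

  # Local slice around the anchor; CG start positions in genomic coordinates.
  lo <- max(0L, pos - max_len)
  hi <- min(clen, pos + max_len + 1L)
  slice <- genome_fetch(genome, chrom, lo, hi)
  cg_local <- gregexpr("CG", slice, fixed = TRUE)[[1]]
  cg_local <- cg_local[cg_local > 0]
  cg_pos <- lo + as.integer(cg_local) - 1L  # 0-based genomic start of each CG

  res <- list()
  for (L in seq.int(min_len, max_len)) {
    # anchor CG (pos, pos+1) must be fully inside: start <= pos, start+L >= pos+2
    s0 <- max(0L, pos - L + 2L)
    s1 <- min(pos, clen - L)
    if (s0 > s1) next
    starts <- seq.int(s0, s1)
    ncg <- vapply(starts, function(s)
      sum(cg_pos >= s & cg_pos + 2L <= s + L), integer(1))
    ok <- ncg >= min_cpgs & ncg <= max_cpgs
    if (any(ok))
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = starts[ok], end = starts[ok] + L,
        length_nt = L, n_cpgs = ncg[ok], anchor_pos = pos,
        stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      length_nt = integer(), n_cpgs = integer(),
                      anchor_pos = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(-out$n_cpgs, out$length_nt, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write epimutation calls as BED6+
#'
#' BED columns: chrom, start, end (the CpG dinucleotide), name = rank,
#' score = round(1000 * |delta|), strand, then delta, p_value, q_value,
#' mean_case, mean_control.
#'
#' @param calls Call table from [call_epimutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%g\t%g\t%g\t%g\t%g",
                   calls$chrom, calls$pos, calls$pos + 2L, calls$rank,
                   as.integer(round(1000 * abs(calls$delta))),
                   ifelse(calls$strand == ".", ".", calls$strand),
                   calls$delta, calls$p_value, calls$q_value,
                   calls$mean_case, calls$mean_control)
  writeLines(lines, path)
  invisible(path)
}
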