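# Transcript models, GTF I/O, spliced sequence extraction, read QC, RPKM.

#' Construct a transcript model
#'
#' A stranded multi-exon transcript with genomic exon intervals in 0-based
#' half-open coordinates, sorted by start and non-overlapping.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or 2-column matrix) with `start` and `end`
#'   (0-based half-open).
#' @param source_tag `"assembled"` (default) or `"annotated"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source_tag = c("assembled", "annotated")) {
  source_tag <- match.arg(source_tag)
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, 1:2]
  names(exons) <- c("start", "end")
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start))
    stop(sprintf("transcript '%s': exon with end <= start", transcript_id),
         call. = FALSE)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop(sprintf("transcript '%s': overlapping exons", transcript_id),
         call. = FALSE)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 source_tag = source_tag),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%d-%d(%s), %d exon(s), %d nt [%s]\n",
              x$transcript_id, x$gene_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons),
              transcript_length(x), x$source_tag))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param model A `transcript_model`.
#' @return Sum of exon lengths in nt.
#' @export
transcript_length <- function(model) {
  sum(model$exons$end - model$exons$start)
}

# Genomic span [start, end) of a transcript model.
transcript_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

# Flatten a list of transcript_model into a span table.
transcript_table <- function(models) {
  if (length(models) == 0)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), n_exons = integer(),
                      length_nt = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(models, function(m) {
    sp <- transcript_span(m)
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               chrom = m$chrom, start = unname(sp["start"]),
               end = unname(sp["end"]), strand = m$strand,
               n_exons = nrow(m$exons), length_nt = transcript_length(m),
               stringsAsFactors = FALSE)
  }))
}

#' Read transcript models from a GTF file
#'
#' Parses exon features (Ensembl/Cufflinks attribute dialect) and groups them
#' by `transcript_id`. GTF 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention. An exon without a `transcript_id`
#' attribute, mixed strands within a transcript, or overlapping exons raise a
#' parse error naming the offending line or transcript.
#'
#' @param path GTF path.
#' @param source_tag Tag recorded on every model: `"assembled"` or
#'   `"annotated"`.
#' @return List of [transcript_model()] objects, ordered by first appearance.
#' @export
read_gtf <- function(path, source_tag = c("assembled", "annotated")) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) stop_parse(path, i, "expected 9 tab-separated columns")
    if (f[3] != "exon") next
    attr_str <- f[9]
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", attr_str)
    if (identical(tid, attr_str) || !grepl('transcript_id "', attr_str, fixed = TRUE))
      stop_parse(path, i, "exon feature missing transcript_id attribute")
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", attr_str)
    if (identical(gid, attr_str) || !grepl('gene_id "', attr_str, fixed = TRUE))
      stop_parse(path, i, "exon feature missing gene_id attribute")
    if (!f[7] %in% c("+", "-"))
      stop_parse(path, i, sprintf("invalid strand '%s'", f[7]))
    recs[[length(recs) + 1L]] <- list(tid = tid, gid = gid, chrom = f[1],
                                      start = to0based(f[4]),
                                      end = as.integer(f[5]),
                                      strand = f[7], line = i)
  }
  if (length(recs) == 0) return(list())
  tid_all <- vapply(recs, `[[`, character(1), "tid")
  models <- list()
  for (tid in unique(tid_all)) {
    rs <- recs[tid_all == tid]
    strands <- unique(vapply(rs, `[[`, character(1), "strand"))
    if (length(strands) > 1)
      stop_parse(path, rs[[2]]$line,
                 sprintf("mixed strands within transcript '%s'", tid))
    chroms <- unique(vapply(rs, `[[`, character(1), "chrom"))
    if (length(chroms) > 1)
      stop_parse(path, rs[[2]]$line,
                 sprintf("mixed chromosomes within transcript '%s'", tid))
    exons <- data.frame(start = vapply(rs, `[[`, integer(1), "start"),
                        end = vapply(rs, `[[`, integer(1), "end"))
    models[[tid]] <- transcript_model(tid, rs[[1]]$gid, chroms, strands,
                                      exons, source_tag)
  }
  unname(models)
}

#' Write transcript models as GTF
#'
#' Inverse of [read_gtf()]: one `exon` feature per exon, 1-based inclusive
#' coordinates, Ensembl-style attributes. Round-trips bit-exactly through
#' [read_gtf()].
#'
#' @param models List of `transcript_model`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "epilnc") {
  lines <- unlist(lapply(models, function(m) {
    sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            m$chrom, source, to1based(m$exons$start), m$exons$end,
            m$strand, m$gene_id, m$transcript_id)
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in genomic order and reverse-complements
#' the whole product when the transcript is on the minus strand. Soft-masked
#' (lowercase) bases are uppercased.
#'
#' @param model A `transcript_model`.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Uppercase character string of length equal to the spliced length.
#' @export
spliced_sequence <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$exons)), function(i)
    genome_fetch(genome, model$chrom, model$exons$start[i], model$exons$end[i]),
    character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Read-level FASTQ quality filter
#'
#' Keep rule for raw RNA-Seq reads: a read is kept iff its fraction of `N`
#' bases is strictly below `max_n_frac` AND the fraction of bases with Phred
#' quality strictly above `q_threshold` strictly exceeds `min_q_frac`. The
#' printed inequalities are taken literally (all strict); an empty read is
#' discarded.
#'
#' @param seq Character vector of read sequences.
#' @param qual Character vector of Phred+33 quality strings (same lengths).
#' @param max_n_frac Maximum tolerated fraction of `N` bases (exclusive).
#' @param min_q_frac Required fraction of high-quality bases (exclusive).
#' @param q_threshold Phred score a base must strictly exceed to count as
#'   high quality.
#' @return Logical vector: `TRUE` = keep.
#' @export
fastq_quality_filter <- function(seq, qual, max_n_frac = 0.10,
                                 min_q_frac = 0.85, q_threshold = 20L) {
  stopifnot(length(seq) == length(qual))
  mapply(function(s, q) {
    if (nchar(s) != nchar(q))
      stop("sequence/quality length mismatch", call. = FALSE)
    n <- nchar(s)
    if (n == 0) return(FALSE)
    bases <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    phred <- utf8ToInt(q) - 33L
    n_frac <- sum(bases == "N") / n
    hq_frac <- sum(phred > q_threshold) / n
    (n_frac < max_n_frac) && (hq_frac > min_q_frac)
  }, seq, qual, USE.NAMES = FALSE)
}

#' Read a FASTQ file
#'
#' Phred+33 FASTQ reader backed by Biostrings; returns plain vectors suitable
#' for [fastq_quality_filter()].
#'
#' @param path FASTQ path.
#' @return Data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#' @param reads Data frame with `id`, `seq`, `qual` (Phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                             "+", reads$qual)), path)
  invisible(path)
}

#' RPKM expression value
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `1e9 * read_count / (total_mapped * exon_length_nt)`.
#'
#' @param read_count Uniquely mapped read count (non-negative).
#' @param exon_length_nt Summed exon length of the transcript in nt (>= 1).
#' @param total_mapped Total mappable reads in the library (>= 1).
#' @return Numeric RPKM (vectorised).
#' @export
rpkm <- function(read_count, exon_length_nt, total_mapped) {
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1", call. = FALSE)
  if (any(exon_length_nt < 1)) stop("exon_length_nt must be >= 1", call. = FALSE)
  if (any(read_count < 0)) stop("read_count must be >= 0", call. = FALSE)
  1e9 * as.numeric(read_count) /
    (as.numeric(total_mapped) * as.numeric(exon_length_nt))
}

#' Read a transcript read-count table
#'
#' 3-column TSV with header: `transcript_id`, `count`, `library_size`
#' (alignment and counting are external; this ingests their output).
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_counts_table <- function(path) {
  df <- read_tsv(path)
  need <- c("transcript_id", "count", "library_size")
  if (!all(need %in% names(df)))
    stop(sprintf("counts table '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df
}
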