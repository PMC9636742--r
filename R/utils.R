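# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_parse <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, line, msg), call. = FALSE)
}

# All internal coordinates are 0-based half-open; conversion to/from 1-based
# inclusive file formats (bismark-coverage, GTF, BED score display) happens
# only at the I/O boundary.
to0based <- function(pos1) as.integer(pos1) - 1L
to1based <- function(pos0) as.integer(pos0) + 1L

is_count <- function(x) {
  !is.na(suppressWarnings(as.numeric(x))) &
    as.numeric(x) >= 0 &
    as.numeric(x) == floor(as.numeric(x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

# Derive a reproducible child seed from a base seed; kept < 2^31 - 1 so it is
# always a valid R integer seed.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to their first whitespace-delimited token so chromosome names match
#' GTF/coverage-file names.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Fetch [start, end) (0-based half-open) from a DNAStringSet genome as an
# uppercase character string.
genome_fetch <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' not present in genome", chrom), call. = FALSE)
  len <- Biostrings::width(genome[chrom])
  if (start0 < 0 || end0 > len || start0 > end0)
    stop(sprintf("coordinates [%d,%d) out of bounds for '%s' (length %d)",
                 start0, end0, chrom, len), call. = FALSE)
  toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                          start = start0 + 1L, end = end0)))
}
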