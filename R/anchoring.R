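# Anchoring assembled transcripts at epimutation calls and positional
# filtering/classification against the gene annotation.

#' Gene spans of an annotation
#'
#' Span of each gene = union of its transcripts' genomic spans (0-based
#' half-open). Genes spanning multiple chromosomes are an annotation error.
#'
#' @param annotation List of `transcript_model` (typically
#'   `source_tag = "annotated"`).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_spans <- function(annotation) {
  tab <- transcript_table(annotation)
  if (nrow(tab) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(tab, tab$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1)
      stop(sprintf("gene '%s' spans multiple chromosomes", g$gene_id[1]),
           call. = FALSE)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# GRanges from a 0-based half-open span table (GRanges is 1-based inclusive).
spans_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

#' Anchor transcripts at epimutation calls
#'
#' A transcript is anchored to a call when the call's CpG position lies within
#' the transcript's genomic span, or within `window_nt` of it. The anchor
#' relation is `exonic` (position inside an exon), `intronic` (inside the span
#' but between exons), or `within_window` (outside the span but within the
#' window); `distance_nt` is 0 for the first two. A transcript may anchor to
#' several calls (one result row each).
#'
#' @param transcripts List of `transcript_model` (assembled).
#' @param calls Call table from [call_epimutations()].
#' @param window_nt Anchor window in nt (default 0: span overlap only,
#'   reflecting reads mapped directly onto the epimutation position).
#' @return Data frame with `transcript_id`, `anchor_rank`, `anchor_chrom`,
#'   `anchor_pos`, `anchor_relation`, `distance_nt`.
#' @export
anchor_transcripts <- function(transcripts, calls, window_nt = 0L) {
  stopifnot(window_nt >= 0)
  empty <- data.frame(transcript_id = character(), anchor_rank = integer(),
                      anchor_chrom = character(), anchor_pos = integer(),
                      anchor_relation = character(), distance_nt = integer(),
                      stringsAsFactors = FALSE)
  if (length(transcripts) == 0 || nrow(calls) == 0) return(empty)
  rows <- list()
  for (m in transcripts) {
    sp <- transcript_span(m)
    for (j in seq_len(nrow(calls))) {
      if (calls$chrom[j] != m$chrom) next
      pos <- calls$pos[j]
      if (pos >= sp["start"] && pos < sp["end"]) {
        in_exon <- any(pos >= m$exons$start & pos < m$exons$end)
        rel <- if (in_exon) "exonic" else "intronic"
        dist <- 0L
      } else {
        dist <- if (pos < sp["start"]) sp["start"] - pos else pos - (sp["end"] - 1L)
        if (dist > window_nt) next
        rel <- "within_window"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = m$transcript_id, anchor_rank = calls$rank[j],
        anchor_chrom = calls$chrom[j], anchor_pos = pos,
        anchor_relation = rel, distance_nt = as.integer(dist),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove candidates inside annotated-gene flanks
#'
#' Drops every candidate whose genomic span overlaps any annotated gene span
#' extended by `flank_nt` on both sides (half-open arithmetic: a candidate
#' starting exactly at `gene_end + flank_nt` is retained). The comparison is
#' strand-blind, except that with `antisense_exempt = TRUE` (default) a
#' candidate whose only overlaps are with opposite-strand genes is retained —
#' antisense lncRNAs overlapping a gene are deliberate survivors of the
#' cascade. Candidate order is preserved.
#'
#' @param candidates List of `transcript_model`.
#' @param annotation List of annotated `transcript_model`.
#' @param flank_nt Symmetric flank in nt (default 1000).
#' @param antisense_exempt Retain candidates overlapping only opposite-strand
#'   genes.
#' @return The retained sublist of `candidates`.
#' @export
flank_filter <- function(candidates, annotation, flank_nt = 1000L,
                         antisense_exempt = TRUE) {
  stopifnot(flank_nt >= 0)
  if (length(candidates) == 0) return(candidates)
  genes <- gene_spans(annotation)
  if (nrow(genes) == 0) return(candidates)
  ext <- genes
  ext$start <- pmax(0L, ext$start - as.integer(flank_nt))
  ext$end <- ext$end + as.integer(flank_nt)
  gr_genes <- spans_to_granges(ext)
  cand_tab <- transcript_table(candidates)
  gr_cand <- spans_to_granges(cand_tab)
  hits <- GenomicRanges::findOverlaps(gr_cand, gr_genes, ignore.strand = TRUE)
  keep <- rep(TRUE, length(candidates))
  for (i in unique(S4Vectors::queryHits(hits))) {
    gs <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    opp <- genes$strand[gs] != cand_tab$strand[i]
    keep[i] <- antisense_exempt && all(opp)
  }
  candidates[keep]
}

#' Classify candidate position relative to the annotation
#'
#' Exhaustive, mutually exclusive classes per candidate:
#' \describe{
#'   \item{`sense_overlap`}{some candidate exon overlaps a same-strand gene
#'     span (a candidate inside an annotated intron on the same strand is
#'     sense);}
#'   \item{`antisense_overlap`}{the candidate span overlaps an opposite-strand
#'     gene span and there is no sense overlap;}
#'   \item{`flank_proximal`}{no overlap, but the nearest gene is within
#'     `flank_nt` (0 < distance <= flank_nt);}
#'   \item{`intergenic`}{everything else.}
#' }
#' The nearest gene and its distance are always reported; with an empty
#' annotation the class is `intergenic` with `nearest_distance_nt = Inf`.
#'
#' @param candidates List of `transcript_model`.
#' @param annotation List of annotated `transcript_model`.
#' @param flank_nt Flank distance defining `flank_proximal`.
#' @return Data frame with `transcript_id`, `klass`, `nearest_gene_id`,
#'   `nearest_distance_nt`.
#' @export
classify_position <- function(candidates, annotation, flank_nt = 1000L) {
  genes <- gene_spans(annotation)
  rows <- lapply(candidates, function(m) {
    sp <- transcript_span(m)
    if (nrow(genes) == 0)
      return(data.frame(transcript_id = m$transcript_id, klass = "intergenic",
                        nearest_gene_id = NA_character_,
                        nearest_distance_nt = Inf, stringsAsFactors = FALSE))
    same_chr <- genes[genes$chrom == m$chrom, , drop = FALSE]
    if (nrow(same_chr) == 0)
      return(data.frame(transcript_id = m$transcript_id, klass = "intergenic",
                        nearest_gene_id = NA_character_,
                        nearest_distance_nt = Inf, stringsAsFactors = FALSE))
    # half-open gap between candidate span and each gene span (0 if overlap)
    gap <- pmax(0L, pmax(same_chr$start - sp["end"], sp["start"] - same_chr$end))
    nearest <- which.min(gap)
    overlaps <- gap == 0 &
      (same_chr$start < sp["end"] & sp["start"] < same_chr$end)
    sense <- vapply(which(overlaps & same_chr$strand == m$strand), function(g)
      any(m$exons$start < same_chr$end[g] & same_chr$start[g] < m$exons$end),
      logical(1))
    klass <- if (length(sense) > 0 && any(sense)) {
      "sense_overlap"
    } else if (any(overlaps & same_chr$strand != m$strand)) {
      "antisense_overlap"
    } else if (any(overlaps)) {
      # same-strand gene sitting entirely inside a candidate intron: still a
      # same-strand span overlap, treated as sense
      "sense_overlap"
    } else if (gap[nearest] > 0 && gap[nearest] <= flank_nt) {
      "flank_proximal"
    } else {
      "intergenic"
    }
    data.frame(transcript_id = m$transcript_id, klass = klass,
               nearest_gene_id = same_chr$gene_id[nearest],
               nearest_distance_nt = as.numeric(gap[nearest]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(transcript_id = character(), klass = character(),
               nearest_gene_id = character(), nearest_distance_nt = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
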