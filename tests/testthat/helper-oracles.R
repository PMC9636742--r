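# Independent brute-force oracles used to validate the package's optimised
# implementations. These deliberately share no code with R/.

# All ATG->stop ORFs by naive triplet scan from every ATG position, then
# deduplication of nested ORFs sharing a (frame, end): keep the most 5' ATG.
brute_orfs <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (i in seq_len(max(0, n - 2))) {          # 1-based ATG start
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i
    hit <- NA
    while (j + 2 <= n) {
      cd <- substr(seq, j, j + 2)
      if (j > i && cd %in% stops) { hit <- j; break }
      j <- j + 3
    }
    if (!is.na(hit)) {
      found[[length(found) + 1]] <- data.frame(
        start = i - 1L, end = hit + 2L, frame = (i - 1L) %% 3L,
        open_ended = FALSE)
    } else {
      last_end <- i - 1L + 3L * ((n - i + 1L) %/% 3L)
      found[[length(found) + 1]] <- data.frame(
        start = i - 1L, end = last_end, frame = (i - 1L) %% 3L,
        open_ended = TRUE)
    }
  }
  if (length(found) == 0)
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer(), open_ended = logical()))
  df <- do.call(rbind, found)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$frame <- as.integer(df$frame)
  # nested ORFs share (frame, end): keep the longest (smallest start)
  df <- df[order(df$start), ]
  df <- df[!duplicated(df[c("frame", "end")]), ]
  df$nt_length <- df$end - df$start
  df <- df[order(-df$nt_length, df$start), ]
  rownames(df) <- NULL
  df
}

# Two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins, probabilities from choose().
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  min(1, sum(pr[pr <= pr[xs == a] * (1 + 1e-7)]))
}

# Naive per-base FASTQ keep/discard recount.
naive_fastq_keep <- function(seq, qual, max_n = 0.10, min_q = 0.85, q = 20) {
  n <- nchar(seq)
  if (n == 0) return(FALSE)
  nb <- 0; hq <- 0
  for (i in seq_len(n)) {
    if (toupper(substr(seq, i, i)) == "N") nb <- nb + 1
    if (utf8ToInt(substr(qual, i, i)) - 33 > q) hq <- hq + 1
  }
  (nb / n < max_n) && (hq / n > min_q)
}

# Naive base-by-base spliced sequence extraction.
naive_spliced <- function(model, genome_str) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- character(0)
  for (k in seq_len(nrow(model$exons))) {
    for (p in (model$exons$start[k] + 1):model$exons$end[k])
      out <- c(out, toupper(substr(genome_str, p, p)))
  }
  if (model$strand == "-") out <- rev(unname(comp[out]))
  paste(out, collapse = "")
}

# Random call-table builders for small tests.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

make_calls_df <- function(chrom, pos, rank = seq_along(pos)) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             mean_case = 0.9, mean_control = 0.1, delta = 0.8,
             p_value = 1e-10, q_value = 1e-8, rank = rank,
             n_case_covered = 6L, n_control_covered = 6L,
             stringsAsFactors = FALSE)
}
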