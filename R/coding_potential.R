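# Coding-potential assessment and the six-criterion noncoding filter cascade.
#
# The built-in coding-probability model follows the CPAT design: a logistic
# regression on four sequence features — longest ORF length, ORF coverage,
# Fickett TESTCODE score, and hexamer usage bias — trained on labelled
# coding/noncoding sequences. PFAM and external noncoding scores are ingested
# as scalar tables, never recomputed.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames
#'
#' All ATG-initiated ORFs in the three forward frames of a (strand-resolved)
#' transcript sequence. An ORF runs from an ATG to the next in-frame stop
#' codon (inclusive); when no stop follows before the end of the frame the ORF
#' is reported up to the last complete codon and flagged `open_ended`. Nested
#' ORFs sharing a stop keep only the longest (most 5' ATG). Codons containing
#' `N` never match ATG or a stop. Results are sorted by `nt_length`
#' descending, ties by smaller `start`.
#'
#' @param seq Nucleotide sequence (alphabet A/C/G/T/N; case-insensitive).
#' @return Data frame with 0-based half-open `start`, `end`, `frame` (0-2),
#'   `nt_length` (divisible by 3, stop included), `peptide_length_aa`
#'   (`nt_length/3 - 1`), and logical `open_ended`.
#' @export
find_orfs <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer(), peptide_length_aa = integer(),
                      open_ended = logical())
  if (n < 3) return(empty)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 1) next
    cs <- as.integer(frame + 3L * (seq_len(n_codons) - 1L) + 1L)  # 1-based codon starts
    codons <- substring(seq, cs, cs + 2)
    orf_start <- NA_integer_
    for (k in seq_len(n_codons)) {
      cd <- codons[k]
      if (is.na(orf_start)) {
        if (cd == "ATG") orf_start <- cs[k] - 1L  # 0-based
      } else if (cd %in% STOP_CODONS) {
        end0 <- cs[k] + 2L  # 0-based half-open end == 1-based inclusive end
        out[[length(out) + 1L]] <- c(orf_start, end0, frame, 0L)
        orf_start <- NA_integer_
      }
    }
    if (!is.na(orf_start)) {
      end0 <- cs[n_codons] + 2L
      out[[length(out) + 1L]] <- c(orf_start, end0, frame, 1L)
    }
  }
  if (length(out) == 0) return(empty)
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  df <- data.frame(start = m[, 1], end = m[, 2], frame = m[, 3],
                   nt_length = m[, 2] - m[, 1],
                   peptide_length_aa = (m[, 2] - m[, 1]) %/% 3L - 1L,
                   open_ended = m[, 4] == 1L)
  df <- df[order(-df$nt_length, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Longest ORF (first row of find_orfs), or NULL.
longest_orf <- function(seq) {
  orfs <- find_orfs(seq)
  if (nrow(orfs) == 0) NULL else orfs[1, , drop = FALSE]
}

# Fickett (1982) TESTCODE lookup tables: probability that a sequence with the
# given positional-bias value (rows, thresholds descending 1.9 ... 0.0) or
# base content (thresholds 0.33 ... 0) is coding, plus the weights each
# parameter receives in the combined score. These are the published constants
# also used by CPAT.
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_POSITION_PROB <- list(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.52, 0.41, 0.31, 0.17),
  T = c(0.51, 0.60, 0.69, 0.64, 0.53, 0.48, 0.44, 0.40, 0.30, 0.33))
FICKETT_POSITION_WEIGHT <- c(A = 0.062, C = 0.093, G = 0.205, T = 0.154)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.46, 0.38, 0.37, 0.36, 0.31, 0.33),
  G = c(0.21, 0.40, 0.47, 0.50, 0.52, 0.56, 0.57, 0.52, 0.44, 0.23),
  T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.52, 0.57, 0.60, 0.51))
FICKETT_CONTENT_WEIGHT <- c(A = 0.084, C = 0.076, G = 0.081, T = 0.055)

fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1]]
}

#' Fickett TESTCODE score
#'
#' Classic statistic separating coding from noncoding nucleotide sequence via
#' base positional bias and composition. For each base B, the position value
#' is `max_i count(B at positions == i mod 3) / (min_i count + 1)` and the
#' content value is the frequency of B among A/C/G/T bases; both are mapped to
#' coding probabilities through Fickett's published lookup tables and combined
#' with the published weights. Scores lie in roughly \[0.2, 1.11\]; higher
#' means more coding-like.
#'
#' @param seq Nucleotide sequence (length >= 2). Non-ACGT bases are ignored
#'   for counting; if they exceed 50% of the sequence the score is undefined
#'   and an error is raised.
#' @return Numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2) stop("fickett_score needs length >= 2", call. = FALSE)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- bases %in% c("A", "C", "G", "T")
  if (mean(!acgt) > 0.5)
    stop("undefined Fickett score: > 50% non-ACGT bases", call. = FALSE)
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  n_acgt <- sum(acgt)
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(ph) sum(bases == b & phase == ph & acgt),
                  numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- if (n_acgt > 0) sum(cnt) / n_acgt else 0
    score <- score +
      fickett_lookup(pos_val, FICKETT_POSITION_PARA, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(cont_val, FICKETT_CONTENT_PARA, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste, collapse = ""))
}

count_hexamers <- function(seqs, step) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  colSums(Biostrings::oligonucleotideFrequency(x, width = 6, step = step))
}

#' Train a hexamer usage-bias table
#'
#' Log-likelihood ratio of 6-mer frequencies between coding and noncoding
#' training sequences, the core compositional feature of CPAT-style models.
#' Coding sequences are expected to be ORFs/CDS and are counted in frame
#' (`coding_step = 3`); noncoding sequences are counted in all frames
#' (`noncoding_step = 1`). Both distributions are add-one smoothed over the
#' 4096 hexamers.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of training sequences
#'   (each set >= 10 sequences).
#' @param coding_step,noncoding_step Step sizes for hexamer counting.
#' @return An object of class `hexamer_table`: list with `log_ratio` (named
#'   numeric, 4096 entries, `log(f_coding / f_noncoding)`), `f_coding`,
#'   `f_noncoding`.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs,
                                coding_step = 3L, noncoding_step = 1L) {
  if (length(coding_seqs) < 10 || length(noncoding_seqs) < 10)
    stop("each training set needs >= 10 sequences", call. = FALSE)
  cc <- count_hexamers(coding_seqs, coding_step) + 1
  nc <- count_hexamers(noncoding_seqs, noncoding_step) + 1
  f_c <- cc / sum(cc)
  f_n <- nc / sum(nc)
  structure(list(log_ratio = log(f_c / f_n), f_coding = f_c, f_noncoding = f_n),
            class = "hexamer_table")
}

#' Hexamer usage-bias score of a sequence
#'
#' Mean log-ratio over the in-frame hexamers (offsets 0, 3, 6, ...) of the
#' sequence's longest ORF; 0 when the sequence has no ORF or the ORF is
#' shorter than 6 nt. Hexamers containing non-ACGT bases are skipped.
#'
#' @param seq Nucleotide sequence.
#' @param table A `hexamer_table` from [train_hexamer_table()].
#' @return Numeric score (positive = coding-like).
#' @export
hexamer_score <- function(seq, table) {
  stopifnot(inherits(table, "hexamer_table"))
  orf <- longest_orf(seq)
  if (is.null(orf) || orf$nt_length < 6) return(0)
  oseq <- toupper(substr(seq, orf$start + 1L, orf$end))
  starts <- seq(1L, nchar(oseq) - 5L, by = 3L)
  hex <- substring(oseq, starts, starts + 5L)
  vals <- table$log_ratio[hex]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Coding-feature assessment of transcript sequences
#'
#' Computes, per sequence: spliced length, longest-ORF length and coverage,
#' Fickett TESTCODE score, and hexamer usage bias. This is the feature table
#' consumed by [train_coding_model()] and [coding_probability()].
#'
#' @param seqs Named character vector of transcript sequences (names are
#'   transcript ids).
#' @param hexamer_table A `hexamer_table`.
#' @return Data frame with `transcript_id`, `length_nt`, `orf_nt` (0 if no
#'   ORF), `orf_start`, `orf_coverage`, `fickett`, `hexamer`.
#' @export
assess_coding <- function(seqs, hexamer_table) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    orf <- longest_orf(s)
    orf_nt <- if (is.null(orf)) 0L else orf$nt_length
    orf_start <- if (is.null(orf)) NA_integer_ else orf$start
    data.frame(transcript_id = ids[i], length_nt = nchar(s),
               orf_nt = orf_nt, orf_start = orf_start,
               orf_coverage = orf_nt / nchar(s),
               fickett = fickett_score(s),
               hexamer = hexamer_score(s, hexamer_table),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

CODING_MODEL_FEATURES <- c("orf_nt", "orf_coverage", "fickett", "hexamer")

#' Train the logistic coding-probability model
#'
#' Logistic regression of coding status on the four CPAT-style features
#' (`orf_nt`, `orf_coverage`, `fickett`, `hexamer`). Perfect separation of a
#' synthetic training set is tolerated (glm convergence warnings are
#' suppressed); degenerate single-class input is an error.
#'
#' @param assessments Feature table from [assess_coding()].
#' @param labels Logical (or 0/1) vector: `TRUE` = coding.
#' @return Object of class `coding_model` (intercept + feature coefficients).
#' @export
train_coding_model <- function(assessments, labels) {
  labels <- as.logical(labels)
  stopifnot(nrow(assessments) == length(labels))
  if (length(unique(labels)) < 2)
    stop("training error: both coding and noncoding labels required",
         call. = FALSE)
  df <- assessments[, CODING_MODEL_FEATURES]
  df$y <- as.integer(labels)
  fit <- suppressWarnings(
    stats::glm(y ~ orf_nt + orf_coverage + fickett + hexamer,
               data = df, family = stats::binomial()))
  structure(list(coef = stats::coef(fit), features = CODING_MODEL_FEATURES),
            class = "coding_model")
}

#' Coding probability of assessed transcripts
#'
#' @param model A `coding_model`.
#' @param assessments Feature table from [assess_coding()].
#' @return Numeric vector of probabilities in \[0, 1\] that each transcript is
#'   coding.
#' @export
coding_probability <- function(model, assessments) {
  stopifnot(inherits(model, "coding_model"))
  X <- cbind(1, as.matrix(assessments[, model$features]))
  as.numeric(stats::plogis(X %*% model$coef))
}

#' Save / load a coding model
#'
#' Coefficients are serialized as decimal strings with 17 significant digits
#' (JSON), so a saved-then-loaded model reproduces probabilities bit
#' identically.
#'
#' @param model A `coding_model`.
#' @param path JSON path.
#' @return `path` invisibly (save); a `coding_model` (load).
#' @export
save_coding_model <- function(model, path) {
  stopifnot(inherits(model, "coding_model"))
  obj <- list(format = "epilnc_coding_model", version = 1L,
              features = model$features,
              coef = as.list(stats::setNames(sprintf("%.17g", model$coef),
                                             names(model$coef))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_coding_model
#' @export
load_coding_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "epilnc_coding_model"))
    stop(sprintf("'%s' is not a coding model file", path), call. = FALSE)
  cf <- vapply(obj$coef, function(v) as.numeric(v), numeric(1))
  structure(list(coef = cf, features = unlist(obj$features)),
            class = "coding_model")
}

#' Read an external PFAM best-E-value table
#'
#' TSV with header columns `transcript_id` and `best_evalue`. Protein-domain
#' search itself is external; only its scalar summary is ingested.
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_pfam_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("transcript_id", "best_evalue") %in% names(df)))
    stop(sprintf("PFAM table '%s' needs columns transcript_id, best_evalue",
                 path), call. = FALSE)
  df
}

#' Read an external noncoding-score table
#'
#' TSV with header columns `transcript_id` and `score` (e.g. an iSeeRNA-style
#' noncoding score in \[0, 1\]).
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_noncoding_scores <- function(path) {
  df <- read_tsv(path)
  if (!all(c("transcript_id", "score") %in% names(df)))
    stop(sprintf("score table '%s' needs columns transcript_id, score", path),
         call. = FALSE)
  df
}

#' Default cascade configuration
#'
#' Thresholds of the six-criterion noncoding filter cascade: transcript
#' length > 200 nt; longest ORF < 400 nt; PFAM best E-value > 1e-5 (or no
#' hit); external noncoding score > 0.5; coding-probability threshold 0.375;
#' removal within 1 kb flanks of annotated genes.
#'
#' `cpat_direction` controls the coding-probability criterion:
#' `"noncoding_below"` (default) keeps
#' transcripts with coding probability *below* the threshold, the reading
#' consistent with screening *for* noncoding transcripts; `"literal_above"`
#' keeps transcripts above it.
#'
#' @param length_min,orf_max,pfam_evalue_min,noncoding_score_min,cpat_threshold,flank_nt
#'   Numeric thresholds (see description).
#' @param cpat_direction `"noncoding_below"` or `"literal_above"`.
#' @return Named list of thresholds.
#' @export
cascade_config <- function(length_min = 200L, orf_max = 400L,
                           pfam_evalue_min = 1e-5, noncoding_score_min = 0.5,
                           cpat_threshold = 0.375,
                           cpat_direction = c("noncoding_below", "literal_above"),
                           flank_nt = 1000L) {
  cpat_direction <- match.arg(cpat_direction)
  stopifnot(length_min >= 0, orf_max > 0, pfam_evalue_min > 0,
            noncoding_score_min >= 0, noncoding_score_min <= 1,
            cpat_threshold >= 0, cpat_threshold <= 1, flank_nt >= 0)
  list(length_min = length_min, orf_max = orf_max,
       pfam_evalue_min = pfam_evalue_min,
       noncoding_score_min = noncoding_score_min,
       cpat_threshold = cpat_threshold, cpat_direction = cpat_direction,
       flank_nt = flank_nt)
}

CASCADE_CRITERIA <- c("length_gt_200", "orf_lt_400", "pfam_no_match",
                      "noncoding_score", "coding_probability", "flank_removal")

#' Apply the six-criterion noncoding filter cascade
#'
#' Evaluates every criterion for every transcript (no short-circuiting — all
#' verdicts are always reported) and combines them into an overall pass/fail.
#' Verdicts are `"pass"`, `"fail"`, or `"skipped"` (criterion not evaluable:
#' missing external table or flank verdict); skipped criteria never count as
#' passed, but only `"fail"` verdicts block the overall pass.
#'
#' Criteria, in reporting order: (1) spliced length strictly > `length_min`;
#' (2) longest ORF strictly < `orf_max` nt, stop codon included — a transcript
#' with no ORF passes; (3) PFAM best E-value > `pfam_evalue_min` or no hit;
#' (4) external noncoding score > `noncoding_score_min`; (5) coding
#' probability versus `cpat_threshold` in the configured direction;
#' (6) retention by the annotation flank filter.
#'
#' @param assessments Feature table from [assess_coding()], with a
#'   `coding_prob` column appended (see [coding_probability()]).
#' @param config Cascade thresholds from [cascade_config()].
#' @param pfam Optional PFAM table ([read_pfam_table()]); `NULL` = skipped.
#' @param noncoding_scores Optional score table ([read_noncoding_scores()]);
#'   `NULL` = skipped.
#' @param flank_pass Optional named logical: `TRUE` if the transcript survived
#'   [flank_filter()]; `NULL` = skipped.
#' @return A `FilterDecision` data frame: `transcript_id`, one verdict column
#'   per criterion, `overall` (`"pass"`/`"fail"`), and `first_failed`
#'   (criterion name or `NA`).
#' @export
apply_filter_cascade <- function(assessments, config = cascade_config(),
                                 pfam = NULL, noncoding_scores = NULL,
                                 flank_pass = NULL) {
  if (!"coding_prob" %in% names(assessments))
    stop("assessments need a 'coding_prob' column (see coding_probability())",
         call. = FALSE)
  ids <- assessments$transcript_id
  n <- length(ids)
  v <- function(ok) ifelse(ok, "pass", "fail")

  length_v <- v(assessments$length_nt > config$length_min)
  orf_v <- v(assessments$orf_nt < config$orf_max)  # orf_nt == 0 when no ORF

  if (is.null(pfam)) {
    pfam_v <- rep("skipped", n)
  } else {
    ev <- pfam$best_evalue[match(ids, pfam$transcript_id)]
    pfam_v <- ifelse(is.na(ev), "pass",  # no hit recorded
                     v(ev > config$pfam_evalue_min))
  }
  if (is.null(noncoding_scores)) {
    nc_v <- rep("skipped", n)
  } else {
    sc <- noncoding_scores$score[match(ids, noncoding_scores$transcript_id)]
    nc_v <- ifelse(is.na(sc), "skipped", v(sc > config$noncoding_score_min))
  }
  cp_v <- if (config$cpat_direction == "noncoding_below")
    v(assessments$coding_prob < config$cpat_threshold)
  else
    v(assessments$coding_prob > config$cpat_threshold)
  if (is.null(flank_pass)) {
    fl_v <- rep("skipped", n)
  } else {
    fp <- flank_pass[ids]
    fl_v <- ifelse(is.na(fp), "skipped", v(as.logical(fp)))
  }

  verdicts <- data.frame(length_gt_200 = length_v, orf_lt_400 = orf_v,
                         pfam_no_match = pfam_v, noncoding_score = nc_v,
                         coding_probability = cp_v, flank_removal = fl_v,
                         stringsAsFactors = FALSE)
  failed <- verdicts == "fail"
  overall <- ifelse(rowSums(failed) == 0, "pass", "fail")
  first_failed <- apply(failed, 1, function(r)
    if (any(r)) CASCADE_CRITERIA[which(r)[1]] else NA_character_)
  out <- cbind(data.frame(transcript_id = ids, stringsAsFactors = FALSE),
               verdicts,
               data.frame(overall = overall, first_failed = first_failed,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
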