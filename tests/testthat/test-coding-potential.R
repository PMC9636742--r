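test_that("find_orfs handles canonical, absent and N-containing cases", {
  o <- find_orfs("ATGAAATAG")
  expect_equal(nrow(o), 1)
  expect_equal(o$nt_length, 9L)
  expect_equal(o$peptide_length_aa, 2L)
  expect_false(o$open_ended)
  expect_equal(nrow(find_orfs("CCCCCCCCC")), 0)   # no ATG
  expect_equal(nrow(find_orfs("")), 0)
  # N poisons both start and stop codons
  expect_equal(nrow(find_orfs("ATNAAATAG")), 0)
  o <- find_orfs("ATGAAATNGAAATAG")                # TNG is not a stop
  expect_equal(o$nt_length, 15L)
  # open-ended ORF flagged when no stop follows
  o <- find_orfs("ATGAAAAAA")
  expect_true(o$open_ended)
  expect_equal(o$nt_length, 9L)
})

test_that("find_orfs matches the brute-force triplet-scan oracle on random sequences", {
  set.seed(202)
  for (i in 1:100) {
    s <- random_seq(sample(50:300, 1))
    got <- find_orfs(s)
    want <- brute_orfs(s)
    expect_equal(got[c("start", "end", "frame", "nt_length", "open_ended")],
                 want[c("start", "end", "frame", "nt_length", "open_ended")],
                 ignore_attr = TRUE)
    # stop-terminated ORFs: peptide * 3 + 3 == nt_length
    st <- got[!got$open_ended, ]
    expect_true(all(st$peptide_length_aa * 3 + 3 == st$nt_length))
  }
})

test_that("fickett_score reproduces the hand-walked poly-A constant and is deterministic", {
  # poly-A: position ratios 1.0-bin for A and 0-bin for C/G/T; content 1.0
  # for A and 0 for the rest; weighted sum of the table entries = 0.24869
  expect_equal(fickett_score(strrep("A", 120)), 0.24869, tolerance = 1e-9)
  s <- strrep("ACGT", 30)
  expect_identical(fickett_score(s), fickett_score(s))
  expect_error(fickett_score("N"), "length")
  expect_error(fickett_score(strrep("N", 100)), "non-ACGT")
})

test_that("fickett_score separates codon-biased coding from uniform noncoding sets", {
  corpus <- simulate_training_transcripts(n_coding = 200, n_noncoding = 200,
                                          seed = 404)
  scores <- vapply(corpus$seqs, fickett_score, numeric(1))
  expect_gt(mean(scores[corpus$labels]), mean(scores[!corpus$labels]))
})

test_that("hexamer table: symmetric input gives zero log-ratios, probabilities conserve", {
  set.seed(9)
  seqs <- vapply(rep(300, 12), random_seq, character(1))
  tab <- train_hexamer_table(seqs, seqs, coding_step = 1, noncoding_step = 1)
  expect_true(all(abs(tab$log_ratio) < 1e-12))
  # smoothed coding distribution recovered via the noncoding weights sums to 1
  corpus <- simulate_training_transcripts(50, 50, seed = 5)
  tab2 <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  expect_equal(sum(tab2$f_noncoding * exp(tab2$log_ratio)), 1, tolerance = 1e-9)
  expect_error(train_hexamer_table(seqs[1:3], seqs), ">= 10")
})

test_that("planted codon bias dominates the top hexamer log-ratios", {
  corpus <- simulate_training_transcripts(150, 150, seed = 31,
                                          codon_bias_strength = 1)
  tab <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  top <- names(sort(tab$log_ratio, decreasing = TRUE))[1:50]
  # planted bias prefers G/C in the third codon position; in-frame hexamers
  # are two codons, so positions 3 and 6 should be G/C-enriched at the top
  third <- c(substr(top, 3, 3), substr(top, 6, 6))
  expect_gt(mean(third %in% c("G", "C")), 0.7)
})

test_that("hexamer_score: no-ORF zero, single-hexamer identity, sliding oracle", {
  corpus <- simulate_training_transcripts(20, 20, seed = 8)
  tab <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  expect_equal(hexamer_score("CCCCCCCCCCCC", tab), 0)
  # single-hexamer ORF: ATG + stop = exactly one in-frame hexamer
  one <- "ATGTAA"
  expect_equal(hexamer_score(one, tab), unname(tab$log_ratio["ATGTAA"]))
  # naive sliding-window oracle over the longest ORF
  set.seed(12)
  for (i in 1:50) {
    s <- random_seq(200)
    orf <- find_orfs(s)
    got <- hexamer_score(s, tab)
    if (nrow(orf) == 0 || orf$nt_length[1] < 6) {
      expect_equal(got, 0)
    } else {
      oseq <- substr(s, orf$start[1] + 1, orf$end[1])
      vals <- c()
      k <- 1
      while (k + 5 <= nchar(oseq)) {
        vals <- c(vals, tab$log_ratio[substr(oseq, k, k + 5)])
        k <- k + 3
      }
      expect_equal(got, mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("logistic model separates planted classes and round-trips bit-exactly", {
  # lengths >= 700 nt make the classes separable by construction: planted
  # mRNA ORFs cover ~70% of the transcript, lncRNA ORFs are capped at 300 nt
  corpus <- simulate_training_transcripts(100, 100, seed = 77,
                                          length_range = c(700L, 1500L))
  tab <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  assessments <- assess_coding(corpus$seqs, tab)
  model <- train_coding_model(assessments, corpus$labels)
  prob <- coding_probability(model, assessments)
  expect_equal(mean((prob > 0.5) == corpus$labels), 1.0)  # separable by design
  # degenerate single-class input
  expect_error(train_coding_model(assessments[corpus$labels, ],
                                  rep(TRUE, sum(corpus$labels))), "both")
  # serialization round-trip is bit-identical
  f <- withr::local_tempfile(fileext = ".json")
  save_coding_model(model, f)
  model2 <- load_coding_model(f)
  expect_identical(coding_probability(model2, assessments), prob)
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  corpus <- simulate_training_transcripts(100, 100, seed = 13)
  tab <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  assessments <- assess_coding(corpus$seqs, tab)
  set.seed(14)
  labels <- sample(corpus$labels)          # permutation null
  # 2-fold cross-validation
  n <- length(labels)
  fold <- rep(1:2, length.out = n)
  acc <- numeric(2)
  for (f in 1:2) {
    tr <- fold != f
    m <- train_coding_model(assessments[tr, ], labels[tr])
    p <- coding_probability(m, assessments[!tr, ])
    acc[f] <- mean((p > 0.5) == labels[!tr])
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 0.05)
})

test_that("filter cascade verdicts follow the printed thresholds", {
  mk_assess <- function(id, len, orf, prob) {
    data.frame(transcript_id = id, length_nt = len, orf_nt = orf,
               orf_start = 0L, orf_coverage = orf / len, fickett = 0.5,
               hexamer = 0, coding_prob = prob, stringsAsFactors = FALSE)
  }
  # the three RACE transcript lengths all pass the length criterion
  a <- rbind(mk_assess("t888", 888, 84, 0.1), mk_assess("t603", 603, 84, 0.1),
             mk_assess("t382", 382, 84, 0.1), mk_assess("t200", 200, 84, 0.1))
  d <- apply_filter_cascade(a)
  expect_equal(d$length_gt_200, c("pass", "pass", "pass", "fail"))
  # strict boundary: exactly 200 nt fails
  expect_equal(d$first_failed[4], "length_gt_200")
  # ORF boundary: 399 passes, 400 fails; no ORF passes
  a2 <- rbind(mk_assess("a", 1000, 399, 0.1), mk_assess("b", 1000, 400, 0.1),
              mk_assess("c", 1000, 0, 0.1))
  d2 <- apply_filter_cascade(a2)
  expect_equal(d2$orf_lt_400, c("pass", "fail", "pass"))
  # coding probability, default direction: keep below 0.375
  a3 <- rbind(mk_assess("lo", 1000, 90, 0.374), mk_assess("hi", 1000, 90, 0.376))
  d3 <- apply_filter_cascade(a3)
  expect_equal(d3$coding_probability, c("pass", "fail"))
  # literal direction flips it
  d3b <- apply_filter_cascade(a3, cascade_config(cpat_direction = "literal_above"))
  expect_equal(d3b$coding_probability, c("fail", "pass"))
})

test_that("external tables: skipped when missing, thresholded when present", {
  a <- data.frame(transcript_id = c("x", "y"), length_nt = 500, orf_nt = 90,
                  orf_start = 0L, orf_coverage = 0.2, fickett = 0.5,
                  hexamer = 0, coding_prob = 0.1, stringsAsFactors = FALSE)
  d <- apply_filter_cascade(a)
  expect_true(all(d$pfam_no_match == "skipped"))
  expect_true(all(d$noncoding_score == "skipped"))
  expect_true(all(d$flank_removal == "skipped"))
  expect_equal(d$overall, c("pass", "pass"))  # skipped never fails
  pfam <- data.frame(transcript_id = "x", best_evalue = 1e-10)
  nc <- data.frame(transcript_id = c("x", "y"), score = c(0.9, 0.4))
  d2 <- apply_filter_cascade(a, pfam = pfam, noncoding_scores = nc,
                             flank_pass = c(x = TRUE, y = FALSE))
  expect_equal(d2$pfam_no_match, c("fail", "pass"))  # strong hit fails; no hit passes
  expect_equal(d2$noncoding_score, c("pass", "fail"))
  expect_equal(d2$flank_removal, c("pass", "fail"))
  expect_equal(d2$overall, c("fail", "fail"))
  expect_equal(d2$first_failed, c("pfam_no_match", "noncoding_score"))
})

test_that("cascade separates planted mRNAs from planted lncRNAs with a disjointly trained model", {
  scorer <- default_coding_model(seed = 2026, n_each = 120)
  test_corpus <- simulate_training_transcripts(200, 200, seed = 2027,
                                               length_range = c(300L, 1200L))
  assessments <- assess_coding(test_corpus$seqs, scorer$hexamer_table)
  assessments$coding_prob <- coding_probability(scorer$model, assessments)
  d <- apply_filter_cascade(assessments)
  noncoding_pass <- d$overall[!test_corpus$labels] == "pass"
  mrna_pass <- d$overall[test_corpus$labels] == "pass"
  expect_gte(mean(noncoding_pass), 0.9)   # sensitivity for lncRNA-like
  expect_lte(mean(mrna_pass), 0.1)        # mRNA leakage
})

test_that("scores are pure functions of their inputs", {
  corpus <- simulate_training_transcripts(20, 20, seed = 3)
  tab <- train_hexamer_table(corpus$orf_seqs, unname(corpus$seqs[!corpus$labels]))
  s <- corpus$seqs[[1]]
  expect_identical(c(fickett_score(s), hexamer_score(s, tab)),
                   c(fickett_score(s), hexamer_score(s, tab)))
  a <- assess_coding(corpus$seqs[1:5], tab)
  expect_identical(a, assess_coding(corpus$seqs[1:5], tab))
})
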