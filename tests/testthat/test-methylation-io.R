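test_that("bismark-coverage rows are parsed with 1-based to 0-based conversion", {
  f <- withr::local_tempfile()
  writeLines("chr21\t5010\t5010\t90.0\t9\t1", f)
  tb <- read_methylation_calls(f)
  expect_equal(tb$chrom, "chr21")
  expect_equal(tb$pos, 5009L)
  expect_equal(tb$meth, 9L)
  expect_equal(tb$unmeth, 1L)
})

test_that("empty files give empty tables without error", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  tb <- read_methylation_calls(f)
  expect_equal(nrow(tb), 0)
})

test_that("malformed rows raise parse errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t10\t10\t50.0\t5\t5", "chr1\t20\t20\t50.0"), f)
  expect_error(read_methylation_calls(f), "line 2")
  writeLines(c("chr1\t10\t10\t50.0\t-3\t5"), f)
  expect_error(read_methylation_calls(f), "line 1")
  writeLines(c("chr1\t10\t10\t50.0\t2.5\t5"), f)
  expect_error(read_methylation_calls(f), "line 1")
})

test_that("inconsistent percentage warns and counts win", {
  f <- withr::local_tempfile()
  writeLines("chr1\t10\t10\t10.0\t9\t1", f)  # counts say 90%
  expect_warning(tb <- read_methylation_calls(f), "counts win")
  expect_equal(tb$meth, 9L)
})

test_that("bedGraph fractions alone are rejected; with counts they parse 0-based", {
  f <- withr::local_tempfile(); cf <- withr::local_tempfile()
  writeLines("chr1\t100\t101\t0.900000", f)
  expect_error(read_methylation_calls(f, dialect = "bedgraph"),
               "companion counts")
  writeLines("chr1\t100\t101\t9\t1", cf)
  tb <- read_methylation_calls(f, dialect = "bedgraph", counts_path = cf)
  expect_equal(tb$pos, 100L)  # already 0-based
  expect_equal(tb$meth, 9L)
})

test_that("write/read round-trips are exact for both dialects", {
  set.seed(42)
  n <- 100
  calls <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(1e6, n), strand = ".",
    meth = rpois(n, 5), unmeth = rpois(n, 5), stringsAsFactors = FALSE)
  calls <- calls[!duplicated(calls[c("chrom", "pos")]), ]
  f <- withr::local_tempfile()
  write_methylation_calls(calls, f, dialect = "bismark_cov")
  back <- read_methylation_calls(f)
  expect_identical(back[c("chrom", "pos", "meth", "unmeth")],
                   calls[c("chrom", "pos", "meth", "unmeth")],
                   ignore_attr = TRUE)
  # second write of the re-read table is byte-identical (column fidelity)
  f2 <- withr::local_tempfile()
  write_methylation_calls(back, f2, dialect = "bismark_cov")
  expect_identical(readLines(f), readLines(f2))

  bg <- withr::local_tempfile(); cf <- withr::local_tempfile()
  write_methylation_calls(calls, bg, dialect = "bedgraph", counts_path = cf)
  back2 <- read_methylation_calls(bg, dialect = "bedgraph", counts_path = cf)
  expect_identical(back2[c("chrom", "pos", "meth", "unmeth")],
                   calls[c("chrom", "pos", "meth", "unmeth")],
                   ignore_attr = TRUE)
})

sample_table <- function(chrom, pos, meth, unmeth, strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             stringsAsFactors = FALSE)
}

test_that("build_matrix unions sites, fills zero coverage, keeps groups", {
  t1 <- sample_table("chr1", c(10, 20), c(5, 5), c(5, 5))
  t2 <- sample_table("chr1", c(30, 40), c(1, 1), c(9, 9))
  m <- build_matrix(list(s1 = t1, s2 = t2),
                    c(s1 = "case", s2 = "control"))
  expect_equal(nrow(m$sites), 4)
  expect_equal(unname(m$meth[1, "s2"]), 0L)   # missing pair = coverage 0
  expect_equal(unname(m$unmeth[3, "s1"]), 0L)
  expect_equal(unname(m$group), c("case", "control"))
  expect_false(is.unsorted(m$sites$pos))
})

test_that("build_matrix scales to the six-vs-six study design", {
  tabs <- lapply(1:12, function(i) sample_table("chr1", c(10, 20), i, i))
  names(tabs) <- sprintf("s%02d", 1:12)
  grp <- setNames(rep(c("case", "control"), each = 6), names(tabs))
  m <- build_matrix(tabs, grp)
  expect_equal(ncol(m$meth), 12)
  expect_equal(sum(m$group == "case"), 6)
  expect_equal(sum(m$group == "control"), 6)
})

test_that("build_matrix rejects duplicate sites and unlabelled samples", {
  dup <- sample_table("chr1", c(10, 10), c(1, 2), c(3, 4))
  ok <- sample_table("chr1", 10, 1, 1)
  expect_error(build_matrix(list(a = dup, b = ok),
                            c(a = "case", b = "control")), "duplicate site")
  expect_error(build_matrix(list(a = ok, b = ok), c(a = "case")),
               "without group label")
})

test_that("merge_strands destrands onto the plus-strand cytosine", {
  t1 <- rbind(sample_table("chr1", 100, 3, 2, "+"),
              sample_table("chr1", 101, 4, 1, "-"))
  t2 <- sample_table("chr1", 100, 1, 1, "+")
  m <- build_matrix(list(a = t1, b = t2), c(a = "case", b = "control"),
                    merge_strands = TRUE)
  expect_equal(nrow(m$sites), 1)
  expect_equal(m$sites$pos, 100L)
  expect_equal(unname(m$meth[1, "a"]), 7L)
  expect_equal(unname(m$unmeth[1, "a"]), 3L)
})

test_that("coverage filter keeps sites covered in both groups and is idempotent/monotone", {
  set.seed(7)
  tabs <- lapply(1:4, function(i)
    sample_table("chr1", seq(0, 990, 10), rpois(100, 10), rpois(100, 10)))
  names(tabs) <- c("c1", "c2", "k1", "k2")
  grp <- c(c1 = "case", c2 = "case", k1 = "control", k2 = "control")
  # plant 20 sites with zero coverage in controls
  for (s in c("k1", "k2")) {
    tabs[[s]]$meth[1:20] <- 0L; tabs[[s]]$unmeth[1:20] <- 0L
  }
  m <- build_matrix(tabs, grp)
  f1 <- filter_by_coverage(m, min_cov = 1, min_fraction_samples = 1)
  cov <- m$meth + m$unmeth
  expected <- sum(rowSums(cov >= 1) == 4)
  expect_equal(nrow(f1$sites), expected)
  expect_lte(nrow(f1$sites), 80)
  # sites covered only in cases are removed
  expect_false(any(f1$sites$pos %in% tabs$k1$pos[1:20]))
  # idempotent
  expect_identical(filter_by_coverage(f1, 1, 1)$sites, f1$sites)
  # monotone in min_cov
  prev <- nrow(m$sites)
  for (mc in c(1, 5, 10, 20)) {
    cur <- nrow(filter_by_coverage(m, mc, 0.5)$sites)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("planted low-coverage sites are removed exactly", {
  set.seed(11)
  n <- 1000
  pos <- seq(0, (n - 1) * 10, 10)
  low <- sample.int(n, 200)
  mk <- function() {
    meth <- rpois(n, 15); unmeth <- rpois(n, 15)
    meth[low] <- 0L; unmeth[low] <- sample(0:4, 200, replace = TRUE)
    sample_table("chr1", pos, meth, unmeth)
  }
  tabs <- list(a = mk(), b = mk())
  m <- build_matrix(tabs, c(a = "case", b = "control"))
  f <- filter_by_coverage(m, min_cov = 5, min_fraction_samples = 1)
  # brute-force count over the planted coverage
  cov <- m$meth + m$unmeth
  expect_equal(nrow(f$sites), sum(rowSums(cov >= 5) == 2))
  expect_equal(nrow(f$sites), n - 200)
})
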