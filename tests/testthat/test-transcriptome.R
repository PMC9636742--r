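test_that("GTF round-trip preserves models bit-exactly", {
  set.seed(21)
  models <- lapply(1:5, function(i) {
    nex <- sample(1:6, 1)
    starts <- sort(sample.int(10000, nex)) * 10L
    transcript_model(sprintf("t%d", i), sprintf("g%d", (i + 1) %/% 2),
                     "chr1", sample(c("+", "-"), 1),
                     data.frame(start = starts,
                                end = starts + sample(50:200, nex, TRUE)))
  })
  f <- withr::local_tempfile()
  write_gtf(models, f)
  back <- read_gtf(f)
  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_identical(back[[i]]$exons, models[[i]]$exons)
    expect_identical(back[[i]]$strand, models[[i]]$strand)
    expect_identical(back[[i]]$gene_id, models[[i]]$gene_id)
  }
  # writing the re-read models reproduces the file byte for byte
  f2 <- withr::local_tempfile()
  write_gtf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GTF parser enforces attributes, strand consistency, exon validity", {
  f <- withr::local_tempfile()
  writeLines('chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g";', f)
  expect_error(read_gtf(f), "transcript_id")
  writeLines(c('chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
               'chr1\tx\texon\t200\t300\t.\t-\t.\tgene_id "g"; transcript_id "t";'),
             f)
  expect_error(read_gtf(f), "mixed strands")
  writeLines(c('chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
               'chr1\tx\texon\t50\t150\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
             f)
  expect_error(read_gtf(f), "overlapping exons")
  # single-exon transcript: length = end - start after 0-based conversion
  writeLines('chr1\tx\texon\t11\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";', f)
  m <- read_gtf(f)[[1]]
  expect_equal(m$exons$start, 10L)
  expect_equal(transcript_length(m), 90L)
})

test_that("structural fixture parses to 7/5/3 exons through the GTF layer", {
  fx <- linc02892_fixture()
  f <- withr::local_tempfile()
  write_gtf(fx$transcripts, f)
  back <- read_gtf(f)
  expect_equal(sort(sapply(back, function(m) nrow(m$exons)),
                    decreasing = TRUE), c(7, 5, 3))
  expect_equal(sort(sapply(back, transcript_length), decreasing = TRUE),
               c(888, 603, 382))
})

test_that("spliced_sequence: strand handling and palindromic reverse complement", {
  genome <- Biostrings::DNAStringSet(c(ctg = "ACGTA"))
  plus <- transcript_model("p", "g", "ctg", "+", data.frame(start = 0, end = 4))
  minus <- transcript_model("m", "g", "ctg", "-", data.frame(start = 0, end = 4))
  expect_equal(spliced_sequence(plus, genome), "ACGT")
  # revcomp("ACGT") == "ACGT": the palindrome is the point
  expect_equal(spliced_sequence(minus, genome), "ACGT")
  bad <- transcript_model("b", "g", "ctg", "+", data.frame(start = 2, end = 9))
  expect_error(spliced_sequence(bad, genome), "out of bounds")
})

test_that("spliced_sequence matches naive per-base extraction on random multi-exon models", {
  set.seed(33)
  gstr <- random_seq(3000)
  genome <- Biostrings::DNAStringSet(c(ctg = gstr))
  for (i in 1:20) {
    nex <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 2800, 60), nex))
    m <- transcript_model("t", "g", "ctg", sample(c("+", "-"), 1),
                          data.frame(start = starts,
                                     end = starts + sample(20:50, nex, TRUE)))
    expect_equal(spliced_sequence(m, genome), naive_spliced(m, gstr))
    expect_equal(nchar(spliced_sequence(m, genome)), transcript_length(m))
  }
})

test_that("read QC rule applies the strict printed inequalities", {
  q30 <- strrep("?", 100)  # '?' = Q30
  # 10 Ns in 100 nt: N fraction not strictly < 10% -> discarded
  r1 <- paste0(strrep("N", 10), random_seq(90))
  expect_false(fastq_quality_filter(r1, q30))
  # 9 Ns -> kept (all bases Q30 > Q20)
  r2 <- paste0(strrep("N", 9), random_seq(91))
  expect_true(fastq_quality_filter(r2, q30))
  # exactly 85 high-quality bases is not > 85% -> discarded; 86 is kept
  qmix <- function(hq) paste0(strrep("I", hq), strrep("#", 100 - hq))  # I=Q40, #=Q2
  s <- random_seq(100)
  expect_false(fastq_quality_filter(s, qmix(85)))
  expect_true(fastq_quality_filter(s, qmix(86)))
  # Q20 does not count as > Q20 ('5' = Q20)
  expect_false(fastq_quality_filter(s, strrep("5", 100)))
  # empty read discarded; length mismatch errors
  expect_false(fastq_quality_filter("", ""))
  expect_error(fastq_quality_filter("ACGT", "II"), "mismatch")
})

test_that("QC decisions match a naive per-base recount on random reads", {
  set.seed(101)
  n <- 1000
  seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    len <- sample(20:60, 1)
    b <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
    seqs[i] <- paste(b, collapse = "")
    # half the reads mostly high quality (keep decided by the N rule), half
    # with a broad quality mix (keep decided by the quality rule)
    qrange <- if (i %% 2 == 0) 25:40 else 2:40
    quals[i] <- intToUtf8(sample(qrange, len, replace = TRUE) + 33)
  }
  got <- fastq_quality_filter(seqs, quals)
  want <- mapply(naive_fastq_keep, seqs, quals, USE.NAMES = FALSE)
  expect_identical(got, want)
  expect_gt(sum(got), 0)       # the random mix contains both outcomes
  expect_gt(sum(!got), 0)
})

test_that("FASTQ write/read round-trips through Biostrings", {
  reads <- data.frame(id = c("r1", "r2"),
                      seq = c("ACGTACGTAC", "GGGTTTAAAC"),
                      qual = c("IIIIIIIIII", "##IIII55II"),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
})

test_that("rpkm follows the closed form and its scaling laws", {
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_error(rpkm(10, 0, 1e6), "exon_length_nt")
  expect_error(rpkm(10, 1000, 0), "total_mapped")
  set.seed(77)
  for (i in 1:200) {
    cnt <- sample.int(1e4, 1); len <- sample.int(1e5, 1)
    tot <- sample.int(1e8, 1)
    # closed-form oracle evaluated independently
    expect_equal(rpkm(cnt, len, tot), 1e9 * cnt / (as.numeric(tot) * len),
                 tolerance = 1e-12)
    # linear in count, inverse in length and library size
    expect_equal(rpkm(2 * cnt, len, tot), 2 * rpkm(cnt, len, tot),
                 tolerance = 1e-12)
    expect_equal(rpkm(cnt, 2 * len, tot), rpkm(cnt, len, tot) / 2,
                 tolerance = 1e-12)
    expect_equal(rpkm(cnt, len, 2 * tot), rpkm(cnt, len, tot) / 2,
                 tolerance = 1e-12)
  }
})
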