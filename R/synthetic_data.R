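# Seeded synthetic fixtures exercising every pipeline stage without any
# external download: genome, annotation, methylation counts with planted
# epimutations, transcripts with planted coding/noncoding character, read
# counts for RPKM, and FASTQ reads for the QC rule.
#
# One global seed fans out to per-component child seeds at fixed offsets, so
# individual components stay reproducible when other parts of the
# configuration change.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 3:1]
  all3 <- apply(g, 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# Codon weights with a tunable preference for G/C in the third position,
# a coarse emulation of mammalian codon usage bias. strength 0 = uniform.
codon_weights <- function(strength) {
  third <- substr(SENSE_CODONS, 3, 3)
  w <- exp(strength * ifelse(third %in% c("G", "C"), 1, -1))
  w / sum(w)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate an mRNA-like transcript sequence
#'
#' Random UTRs around a planted ATG...stop ORF built from codon-biased sense
#' codons. The ORF occupies `orf_nt` of the `length_nt` total (default 70%,
#' rounded to a codon multiple).
#'
#' Uses the current RNG state; seed outside.
#'
#' @param length_nt Total transcript length.
#' @param orf_nt ORF length in nt including start and stop codons (multiple
#'   of 3); default 70% of `length_nt`.
#' @param codon_bias_strength Strength of third-position G/C codon bias
#'   (>= 0; 0 = uniform codon usage).
#' @return Character sequence of length `length_nt`.
#' @export
simulate_coding_seq <- function(length_nt, orf_nt = NULL,
                                codon_bias_strength = 0.5) {
  if (is.null(orf_nt)) orf_nt <- 3L * (floor(0.7 * length_nt) %/% 3L)
  orf_nt <- as.integer(orf_nt)
  if (orf_nt > length_nt)
    stop("configuration error: ORF longer than transcript", call. = FALSE)
  if (orf_nt %% 3 != 0) stop("orf_nt must be a multiple of 3", call. = FALSE)
  if (orf_nt < 9) stop("orf_nt must be >= 9", call. = FALSE)
  n_codons <- orf_nt %/% 3L - 2L
  body <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE,
                       prob = codon_weights(codon_bias_strength)),
                collapse = "")
  orf <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
  utr_total <- length_nt - orf_nt
  u5 <- sample.int(utr_total + 1L, 1) - 1L
  paste0(if (u5 > 0) random_bases(u5) else "",
         orf,
         if (utr_total - u5 > 0) random_bases(utr_total - u5) else "")
}

#' Simulate a lncRNA-like transcript sequence
#'
#' Random bases with stop codons planted into any overlong reading frame so
#' that no ORF reaches `orf_cap` nt, emulating the fragmented ORF structure
#' of noncoding transcripts.
#'
#' Uses the current RNG state; seed outside.
#'
#' @param length_nt Total transcript length.
#' @param orf_cap Maximum allowed ORF length (nt); default 300.
#' @return Character sequence of length `length_nt`.
#' @export
simulate_noncoding_seq <- function(length_nt, orf_cap = 300L) {
  s <- random_bases(length_nt)
  for (it in 1:200) {
    orfs <- find_orfs(s)
    if (nrow(orfs) == 0 || orfs$nt_length[1] < orf_cap) break
    # replace the middle codon of the longest ORF with a stop
    o <- orfs[1, ]
    mid_codon <- o$start + 3L * ((o$nt_length %/% 3L) %/% 2L)
    substr(s, mid_codon + 1L, mid_codon + 3L) <- "TAA"
  }
  s
}

#' Simulate a labelled coding/noncoding training corpus
#'
#' @param n_coding,n_noncoding Set sizes.
#' @param seed RNG seed.
#' @param length_range Transcript length range (nt), sampled uniformly.
#' @param codon_bias_strength Codon bias of the coding set.
#' @return List with `seqs` (named character vector), `labels` (logical,
#'   `TRUE` = coding), and `orf_seqs` (the planted ORF of each coding
#'   sequence, for hexamer training).
#' @export
simulate_training_transcripts <- function(n_coding = 150L, n_noncoding = 150L,
                                          seed = 1L,
                                          length_range = c(300L, 1500L),
                                          codon_bias_strength = 0.5) {
  set.seed(child_seed(seed, 11L))
  lens_c <- sample(seq(length_range[1], length_range[2]), n_coding,
                   replace = TRUE)
  lens_n <- sample(seq(length_range[1], length_range[2]), n_noncoding,
                   replace = TRUE)
  coding <- vapply(lens_c, simulate_coding_seq, character(1),
                   codon_bias_strength = codon_bias_strength)
  noncoding <- vapply(lens_n, simulate_noncoding_seq, character(1))
  orf_seqs <- vapply(coding, function(s) {
    o <- longest_orf(s)
    substr(s, o$start + 1L, o$end)
  }, character(1), USE.NAMES = FALSE)
  seqs <- c(coding, noncoding)
  names(seqs) <- c(sprintf("coding_%03d", seq_len(n_coding)),
                   sprintf("noncoding_%03d", seq_len(n_noncoding)))
  list(seqs = seqs, labels = rep(c(TRUE, FALSE), c(n_coding, n_noncoding)),
       orf_seqs = orf_seqs)
}

#' Built-in coding-probability scorer
#'
#' Trains the hexamer table and logistic coding model on a seeded simulated
#' corpus ([simulate_training_transcripts()]), giving a fully self-contained,
#' deterministic scorer for the filter cascade.
#'
#' @param seed Seed for the training corpus.
#' @param n_each Sequences per class.
#' @return List with `hexamer_table` and `model` (a `coding_model`).
#' @export
default_coding_model <- function(seed = 1L, n_each = 150L) {
  corpus <- simulate_training_transcripts(n_coding = n_each,
                                          n_noncoding = n_each, seed = seed)
  tab <- train_hexamer_table(corpus$orf_seqs,
                             unname(corpus$seqs[!corpus$labels]))
  assessments <- assess_coding(corpus$seqs, tab)
  model <- train_coding_model(assessments, corpus$labels)
  list(hexamer_table = tab, model = model)
}

#' Simulate a case/control methylation matrix
#'
#' The study design of the discovery step: `n_case` vs `n_control` bisulfite
#' samples, per-sample coverage Poisson(`coverage_mean`), methylated counts
#' Binomial(coverage, p).
#'
#' Null sites model a CpG with one fixed underlying methylation level: a
#' single `p ~ Beta(null_shape1, null_shape2)` shared by every sample in both
#' groups. Planted (differential) sites model an epimutation with
#' inter-individual variability: each sample draws its own level from its
#' group's Beta.
#'
#' @param seed RNG seed.
#' @param n_sites Total number of CpG sites.
#' @param n_case,n_control Samples per group.
#' @param coverage_mean Mean per-sample coverage.
#' @param planted Optional data.frame with columns `index`, `case_shape1`,
#'   `case_shape2`, `control_shape1`, `control_shape2`.
#' @param null_shape1,null_shape2 Beta parameters of the null site-level
#'   methylation distribution.
#' @param chrom,pos_step Site coordinates: site i sits at
#'   `pos = (i - 1) * pos_step` on `chrom`.
#' @return A `MethylationMatrix`.
#' @export
simulate_methylation_matrix <- function(seed = 1L, n_sites = 1000L,
                                        n_case = 6L, n_control = 6L,
                                        coverage_mean = 30,
                                        planted = NULL,
                                        null_shape1 = 5, null_shape2 = 5,
                                        chrom = "sim", pos_step = 50L) {
  set.seed(child_seed(seed, 21L))
  ns <- n_case + n_control
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("control_%02d", seq_len(n_control)))
  group <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                           samples)
  p_site <- stats::rbeta(n_sites, null_shape1, null_shape2)
  pmat <- matrix(p_site, n_sites, ns)
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      i <- planted$index[r]
      pmat[i, seq_len(n_case)] <-
        stats::rbeta(n_case, planted$case_shape1[r], planted$case_shape2[r])
      pmat[i, n_case + seq_len(n_control)] <-
        stats::rbeta(n_control, planted$control_shape1[r],
                     planted$control_shape2[r])
    }
  }
  cov <- matrix(stats::rpois(n_sites * ns, coverage_mean), n_sites, ns)
  meth <- matrix(stats::rbinom(n_sites * ns, cov, pmat), n_sites, ns,
                 dimnames = list(NULL, samples))
  unmeth <- cov - meth
  dimnames(unmeth) <- dimnames(meth)
  sites <- data.frame(chrom = chrom, pos = (seq_len(n_sites) - 1L) * pos_step,
                      strand = "+", stringsAsFactors = FALSE)
  structure(list(sites = sites, samples = samples, group = group,
                 meth = meth, unmeth = unmeth),
            class = "MethylationMatrix")
}

#' Simulation configuration for the full fixture
#'
#' Defaults encode the emulated study: six case and six control bisulfite
#' samples, mean coverage 30, 1000 CpG sites of which two are planted
#' epimutations (case levels Beta(9,1) vs control Beta(1,9), i.e. a
#' methylation difference around 0.8) — one under an antisense lncRNA locus
#' together with two mRNA-like decoys, one in an intergenic desert with no
#' transcription.
#'
#' @param seed Global seed; per-component seeds are derived at fixed offsets.
#' @param genome_size_nt Genome length (single chromosome; >= 60000).
#' @param chrom Chromosome name.
#' @param n_genes Number of annotated genes (>= 1; gene 1 hosts the anchor).
#' @param n_case,n_control Samples per group.
#' @param coverage_mean Mean per-sample coverage.
#' @param n_sites Total CpG sites (planted included).
#' @param null_shape1,null_shape2 Beta parameters of null site methylation.
#' @param case_shape,control_shape Length-2 Beta parameters of planted sites.
#' @param codon_bias_strength Codon bias of mRNA-like planted transcripts.
#' @param n_reads,read_length FASTQ read simulation.
#' @param library_size Library size for the RPKM counts table.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_size_nt = 60000L,
                              chrom = "chrS", n_genes = 4L,
                              n_case = 6L, n_control = 6L,
                              coverage_mean = 30, n_sites = 1000L,
                              null_shape1 = 5, null_shape2 = 5,
                              case_shape = c(9, 1), control_shape = c(1, 9),
                              codon_bias_strength = 0.5,
                              n_reads = 200L, read_length = 100L,
                              library_size = 1e6) {
  stopifnot(genome_size_nt >= 60000, n_genes >= 1, n_case >= 1,
            n_control >= 1, coverage_mean > 0, n_sites >= 10,
            n_reads >= 1, read_length >= 10, library_size >= 1)
  structure(list(seed = seed, genome_size_nt = as.integer(genome_size_nt),
                 chrom = chrom, n_genes = as.integer(n_genes),
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 coverage_mean = coverage_mean, n_sites = as.integer(n_sites),
                 null_shape1 = null_shape1, null_shape2 = null_shape2,
                 case_shape = case_shape, control_shape = control_shape,
                 codon_bias_strength = codon_bias_strength,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 library_size = library_size),
            class = "simulation_config")
}

# Split a transcript length into n roughly equal exon lengths.
split_exon_lengths <- function(length_nt, n_exons) {
  base <- length_nt %/% n_exons
  rem <- length_nt %% n_exons
  base + as.integer(seq_len(n_exons) <= rem)
}

# Default planted-transcript table of the fixture.
default_planted_transcripts <- function() {
  data.frame(
    id = c("lnc_planted", "mrna_decoy_1", "mrna_decoy_2",
           "lnc_decoy_1", "mrna_decoy_3"),
    kind = c("antisense-lncRNA", "mRNA-like", "mRNA-like",
             "lncRNA-like", "mRNA-like"),
    length = c(600L, 650L, 540L, 600L, 900L),
    n_exons = c(3L, 2L, 2L, 2L, 1L),
    anchored = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    count = c(250L, 180L, 90L, 40L, 120L),
    stringsAsFactors = FALSE)
}

#' Generate the full synthetic fixture
#'
#' Writes a complete, seeded file bundle under `dir`:
#' \itemize{
#'   \item `genome.fa` — random genome with CpG-density boost around the two
#'     planted epimutation sites;
#'   \item `annotation.gtf` — annotated "coding" genes (gene 1 hosts the
#'     anchor site in its intron);
#'   \item `assembled.gtf` — planted transcripts: an antisense lncRNA over
#'     the anchor site, two anchored mRNA-like decoys (long, codon-biased
#'     ORFs written into the genome), plus unanchored decoys elsewhere;
#'   \item one bismark-coverage file per sample and a `samples.tsv` manifest;
#'   \item `counts.tsv` — per-transcript uniquely-mapped read counts for RPKM
#'     (the planted lncRNA gets 250 reads);
#'   \item `reads.fastq` — reads with a seeded mixture of clean and
#'     low-quality/N-rich records for the QC rule;
#'   \item `truth.tsv` — every planted object.
#' }
#' Re-running with the same configuration reproduces every file byte for
#' byte.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (data.frame), and `config`.
#' @export
generate_fixture <- function(config = simulation_config(), dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- config$genome_size_nt
  chrom <- config$chrom

  # --- genome ---------------------------------------------------------------
  set.seed(child_seed(config$seed, 1L))
  genome_chars <- sample(c("A", "C", "G", "T"), G, replace = TRUE)

  # --- layout ---------------------------------------------------------------
  site1 <- 12000L                     # anchored epimutation (gene 1 intron)
  site2 <- 40000L                     # epimutation in an intergenic desert
  gene1 <- list(start = site1 - 2500L, end = site1 + 2500L, strand = "+")
  # remaining genes, away from both sites
  other_gene_starts <- c(20000L, 30000L, 50000L)
  n_other <- config$n_genes - 1L
  if (n_other > length(other_gene_starts))
    other_gene_starts <- c(other_gene_starts,
                           seq(2000L, 8000L,
                               length.out = n_other - length(other_gene_starts)))
  annotation <- list(transcript_model(
    "gene1.t1", "gene1", chrom, gene1$strand,
    data.frame(start = c(gene1$start, gene1$end - 1000L),
               end = c(gene1$start + 1000L, gene1$end)),
    source_tag = "annotated"))
  if (n_other > 0) {
    for (i in seq_len(n_other)) {
      gs <- as.integer(other_gene_starts[i])
      annotation[[i + 1L]] <- transcript_model(
        sprintf("gene%d.t1", i + 1L), sprintf("gene%d", i + 1L), chrom,
        if (i %% 2 == 0) "+" else "-",
        data.frame(start = c(gs, gs + 2000L), end = c(gs + 800L, gs + 3000L)),
        source_tag = "annotated")
    }
  }

  # --- planted transcripts --------------------------------------------------
  set.seed(child_seed(config$seed, 2L))
  planted <- default_planted_transcripts()
  exclusion <- c(site1 - 100L, site1 + 100L)   # keep the anchor CpG zone free
  left_cursor <- site1 - 1450L                 # inside gene 1's intron
  right_cursor <- exclusion[2] + 20L
  free_cursor <- 24500L                        # intergenic desert for decoys
  models <- list()
  seqs <- character()
  for (r in seq_len(nrow(planted))) {
    id <- planted$id[r]; kind <- planted$kind[r]
    len <- planted$length[r]; nex <- planted$n_exons[r]
    target <- if (kind == "mRNA-like")
      simulate_coding_seq(len, codon_bias_strength = config$codon_bias_strength)
    else
      simulate_noncoding_seq(len)
    exl <- split_exon_lengths(len, nex)
    if (planted$anchored[r]) {
      if (nex < 2)
        stop(sprintf("configuration error: anchored transcript '%s' needs >= 2 exons", id),
             call. = FALSE)
      n_left <- ceiling(nex / 2)
      starts <- integer(nex)
      for (k in seq_len(nex)) {
        if (k <= n_left) {
          starts[k] <- left_cursor
          left_cursor <- left_cursor + exl[k] + 20L
        } else {
          starts[k] <- right_cursor
          right_cursor <- right_cursor + exl[k] + 20L
        }
      }
      if (left_cursor > exclusion[1] || right_cursor > site1 + 1500L)
        stop("configuration error: anchored transcripts do not fit the anchor locus",
             call. = FALSE)
      strand <- "-"
    } else {
      starts <- integer(nex)
      for (k in seq_len(nex)) {
        starts[k] <- free_cursor
        free_cursor <- free_cursor + exl[k] + 50L
      }
      free_cursor <- free_cursor + 400L
      if (free_cursor > 28500L)
        stop("configuration error: unanchored decoys do not fit their region",
             call. = FALSE)
      strand <- "+"
    }
    exons <- data.frame(start = starts, end = starts + exl)
    m <- transcript_model(id, id, chrom, strand, exons,
                          source_tag = "assembled")
    # write the transcript sequence into the genome (minus strand: the
    # genomic content over the exons is the reverse complement of the spliced
    # sequence, laid out in genomic order)
    genomic <- if (strand == "-") revcomp(target) else target
    off <- 0L
    for (k in seq_len(nrow(m$exons))) {
      w <- m$exons$end[k] - m$exons$start[k]
      genome_chars[(m$exons$start[k] + 1L):(m$exons$end[k])] <-
        strsplit(substr(genomic, off + 1L, off + w), "", fixed = TRUE)[[1]]
      off <- off + w
    }
    models[[id]] <- m
    seqs[id] <- target
  }

  # --- CpG sites ------------------------------------------------------------
  # force a CG at each planted site and boost CpG density around it (the
  # anchor zone is kept free of planted exons)
  for (s in c(site1, site2)) {
    for (off in c(0L, seq(-80L, 80L, by = 20L))) {
      p <- s + off
      genome_chars[p + 1L] <- "C"; genome_chars[p + 2L] <- "G"
    }
  }
  genome_seq <- paste(genome_chars, collapse = "")
  set.seed(child_seed(config$seed, 3L))
  cg_all <- as.integer(gregexpr("CG", genome_seq, fixed = TRUE)[[1]]) - 1L
  cg_null <- setdiff(cg_all, c(site1, site2))
  n_null <- config$n_sites - 2L
  if (length(cg_null) < n_null)
    stop("configuration error: genome has too few CpGs for n_sites", call. = FALSE)
  null_pos <- sort(sample(cg_null, n_null))
  site_pos <- sort(c(null_pos, site1, site2))
  planted_idx <- match(c(site1, site2), site_pos)

  # --- methylation counts ---------------------------------------------------
  set.seed(child_seed(config$seed, 4L))
  ns <- config$n_case + config$n_control
  samples <- c(sprintf("case_%02d", seq_len(config$n_case)),
               sprintf("control_%02d", seq_len(config$n_control)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(config$n_case, config$n_control)), samples)
  nsite <- length(site_pos)
  p_site <- stats::rbeta(nsite, config$null_shape1, config$null_shape2)
  pmat <- matrix(p_site, nsite, ns)
  for (i in planted_idx) {
    pmat[i, seq_len(config$n_case)] <-
      stats::rbeta(config$n_case, config$case_shape[1], config$case_shape[2])
    pmat[i, config$n_case + seq_len(config$n_control)] <-
      stats::rbeta(config$n_control, config$control_shape[1],
                   config$control_shape[2])
  }
  cov <- matrix(stats::rpois(nsite * ns, config$coverage_mean), nsite, ns)
  meth <- matrix(stats::rbinom(nsite * ns, cov, pmat), nsite, ns)

  # --- FASTQ reads ----------------------------------------------------------
  set.seed(child_seed(config$seed, 5L))
  rl <- config$read_length
  read_start <- sample.int(G - rl, config$n_reads, replace = TRUE)
  read_seq <- substring(genome_seq, read_start, read_start + rl - 1L)
  read_kind <- sample(c("good", "lowq", "nrich"), config$n_reads,
                      replace = TRUE, prob = c(0.7, 0.15, 0.15))
  quals <- character(config$n_reads)
  for (i in seq_len(config$n_reads)) {
    if (read_kind[i] == "lowq") {
      ph <- sample(2:40, rl, replace = TRUE)   # broad quality: many below Q20
    } else {
      ph <- sample(25:40, rl, replace = TRUE)
      if (read_kind[i] == "nrich") {
        nn <- ceiling(0.15 * rl)
        idx <- sample.int(rl, nn)
        s <- strsplit(read_seq[i], "", fixed = TRUE)[[1]]
        s[idx] <- "N"
        read_seq[i] <- paste(s, collapse = "")
      }
    }
    quals[i] <- intToUtf8(ph + 33L)
  }
  reads <- data.frame(id = sprintf("read_%04d", seq_len(config$n_reads)),
                      seq = read_seq, qual = quals, stringsAsFactors = FALSE)

  # --- write files ----------------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    assembled = file.path(dir, "assembled.gtf"),
    samples = file.path(dir, "samples.tsv"),
    counts = file.path(dir, "counts.tsv"),
    fastq = file.path(dir, "reads.fastq"),
    truth = file.path(dir, "truth.tsv"))

  gset <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
  Biostrings::writeXStringSet(gset, paths$genome, width = 80L)
  write_gtf(annotation, paths$annotation, source = "epilnc_sim")
  write_gtf(unname(models), paths$assembled, source = "epilnc_sim")

  cov_paths <- file.path(dir, paste0(samples, ".cov"))
  for (j in seq_len(ns)) {
    calls <- data.frame(chrom = chrom, pos = site_pos, strand = ".",
                        meth = meth[, j], unmeth = cov[, j] - meth[, j],
                        stringsAsFactors = FALSE)
    write_methylation_calls(calls, cov_paths[j], dialect = "bismark_cov")
  }
  write_tsv(data.frame(sample_id = samples, group = unname(groups),
                       file = basename(cov_paths), stringsAsFactors = FALSE),
            paths$samples)

  write_tsv(data.frame(transcript_id = planted$id, count = planted$count,
                       library_size = as.integer(config$library_size),
                       stringsAsFactors = FALSE), paths$counts)
  write_fastq(reads, paths$fastq)

  truth <- rbind(
    data.frame(type = "epimutation",
               id = c("site1_anchored", "site2_desert"),
               chrom = chrom, start = c(site1, site2),
               end = c(site1, site2) + 2L, strand = "+",
               detail = sprintf("case Beta(%g,%g) vs control Beta(%g,%g)",
                                config$case_shape[1], config$case_shape[2],
                                config$control_shape[1], config$control_shape[2]),
               stringsAsFactors = FALSE),
    data.frame(type = "transcript", id = planted$id, chrom = chrom,
               start = vapply(models[planted$id], function(m)
                 unname(transcript_span(m)["start"]), numeric(1)),
               end = vapply(models[planted$id], function(m)
                 unname(transcript_span(m)["end"]), numeric(1)),
               strand = vapply(models[planted$id], `[[`, character(1), "strand"),
               detail = sprintf("%s%s", planted$kind,
                                ifelse(planted$anchored, "; anchored", "")),
               stringsAsFactors = FALSE),
    data.frame(type = "gene",
               id = vapply(annotation, `[[`, character(1), "gene_id"),
               chrom = chrom,
               start = vapply(annotation, function(m)
                 unname(transcript_span(m)["start"]), numeric(1)),
               end = vapply(annotation, function(m)
                 unname(transcript_span(m)["end"]), numeric(1)),
               strand = vapply(annotation, `[[`, character(1), "strand"),
               detail = "annotated coding gene", stringsAsFactors = FALSE))
  write_tsv(truth, paths$truth)

  paths$coverage <- cov_paths
  invisible(list(paths = paths, truth = truth, config = config))
}

#' Structural fixture of the LINC02892 transcripts
#'
#' Deterministic transcript models reproducing the RACE-determined structure
#' of the three LINC02892 transcripts — spliced lengths 888, 603 and 382 nt
#' with seven, five and three exons respectively — on a toy chromosome
#' (`chr21_toy`), minus strand, together with one overlapping plus-strand
#' annotated gene (the antisense configuration). Internal exon boundaries are
#' arbitrary but fixed.
#'
#' @return List with `transcripts` (3 `transcript_model`s, assembled) and
#'   `annotation` (1 annotated `transcript_model`).
#' @export
linc02892_fixture <- function() {
  spec <- list(c(len = 888L, nex = 7L), c(len = 603L, nex = 5L),
               c(len = 382L, nex = 3L))
  base_start <- c(1000L, 1200L, 1400L)
  transcripts <- lapply(seq_along(spec), function(i) {
    len <- spec[[i]]["len"]; nex <- spec[[i]]["nex"]
    exl <- split_exon_lengths(len, nex)
    starts <- base_start[i] + cumsum(c(0L, exl[-nex] + 150L))
    transcript_model(sprintf("LINC02892.t%d", i), "LINC02892", "chr21_toy",
                     "-", data.frame(start = starts, end = starts + exl),
                     source_tag = "assembled")
  })
  annotation <- list(transcript_model(
    "toygene.t1", "toygene", "chr21_toy", "+",
    data.frame(start = 900L, end = 4200L), source_tag = "annotated"))
  list(transcripts = transcripts, annotation = annotation)
}
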