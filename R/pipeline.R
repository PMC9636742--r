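# End-to-end orchestration: methylation -> epimutation calling -> top-k ->
# anchoring -> noncoding filter cascade -> RPKM -> report.

#' Pipeline configuration
#'
#' All module parameters in one namespaced list. The cascade defaults are the
#' printed discovery thresholds (length > 200 nt, ORF < 400 nt, PFAM E-value
#' > 1e-5, noncoding score > 0.5, coding-probability threshold 0.375, 1 kb
#' flanks) and `top_k = 2` (the two best differential sites are carried
#' forward).
#'
#' @param epimutation List: `min_cov`, `min_fraction_samples` (coverage
#'   filter), `min_abs_delta`, `alpha`.
#' @param top_k Number of top epimutation calls used as anchors.
#' @param anchoring List: `window_nt`, `flank_nt`, `antisense_exempt`.
#' @param cascade Cascade thresholds, see [cascade_config()].
#' @param model_seed Seed of the built-in coding model's training corpus.
#' @param seed Global seed (reserved for stages with randomness).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(epimutation = list(min_cov = 10L,
                                               min_fraction_samples = 0.75,
                                               min_abs_delta = 0.2,
                                               alpha = 0.05),
                            top_k = 2L,
                            anchoring = list(window_nt = 0L,
                                             flank_nt = 1000L,
                                             antisense_exempt = TRUE),
                            cascade = cascade_config(),
                            model_seed = 1L,
                            seed = 1L) {
  if (top_k < 1) stop("configuration error: top_k must be >= 1", call. = FALSE)
  list(epimutation = epimutation, top_k = as.integer(top_k),
       anchoring = anchoring, cascade = cascade,
       model_seed = model_seed, seed = seed)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[epilnc %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the epimutation-anchored lncRNA discovery pipeline
#'
#' Executes the whole discovery cascade and writes every intermediate
#' artifact into `out_dir`:
#' \enumerate{
#'   \item read per-sample methylation call files (manifest), build and
#'     coverage-filter the matrix;
#'   \item call epimutations, write `epimutation_calls.tsv`/`.bed`, keep the
#'     top `top_k`;
#'   \item anchor assembled transcripts at the kept calls
#'     (`anchored.tsv`);
#'   \item apply the annotation flank filter (antisense exemption per
#'     config);
#'   \item assess coding potential with the built-in seeded model, ingest
#'     optional PFAM / noncoding-score tables, apply the six-criterion
#'     cascade (`assessments.tsv`);
#'   \item compute RPKM from the counts table and classify candidate
#'     positions;
#'   \item write `report.tsv` — one row per anchored transcript with every
#'     verdict, position class, RPKM and anchor call.
#' }
#'
#' @param samples_tsv Manifest TSV with columns `sample_id`, `group`
#'   (`case`/`control`), `file` (bismark-coverage path, relative paths
#'   resolved against the manifest's directory).
#' @param assembled_gtf,annotation_gtf GTF paths (assembled transcripts /
#'   gene annotation).
#' @param genome_fa Reference genome FASTA.
#' @param counts_tsv Optional read-count table
#'   ([read_counts_table()]); without it RPKM is `NA`.
#' @param pfam_tsv,noncoding_tsv Optional external score tables.
#' @param out_dir Output directory.
#' @param config [pipeline_config()].
#' @return Invisibly, a list with `calls`, `top`, `anchored`, `assessments`,
#'   `decisions`, `report` (data.frames) and `out_dir`.
#' @export
run_pipeline <- function(samples_tsv, assembled_gtf, annotation_gtf,
                         genome_fa, counts_tsv = NULL, pfam_tsv = NULL,
                         noncoding_tsv = NULL, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage("stage methylation: reading sample manifest '%s'", samples_tsv)
  manifest <- read_tsv(samples_tsv)
  if (!all(c("sample_id", "group", "file") %in% names(manifest)))
    stop("samples manifest needs columns sample_id, group, file", call. = FALSE)
  files <- ifelse(file.exists(manifest$file), manifest$file,
                  file.path(dirname(samples_tsv), manifest$file))
  tables <- lapply(files, read_methylation_calls)
  names(tables) <- manifest$sample_id
  groups <- stats::setNames(manifest$group, manifest$sample_id)
  mat <- build_matrix(tables, groups)
  mat <- filter_by_coverage(mat, config$epimutation$min_cov,
                            config$epimutation$min_fraction_samples)
  log_stage("stage methylation: %d sites x %d samples after coverage filter",
            nrow(mat$sites), length(mat$samples))

  log_stage("stage epimutation: calling differential sites")
  calls <- call_epimutations(mat,
                             min_cov = config$epimutation$min_cov,
                             min_abs_delta = config$epimutation$min_abs_delta,
                             alpha = config$epimutation$alpha)
  write_tsv(calls, file.path(out_dir, "epimutation_calls.tsv"))
  write_calls_bed(calls, file.path(out_dir, "epimutation_calls.bed"))
  top <- top_candidates(calls, config$top_k)
  log_stage("stage epimutation: %d calls, keeping top %d", nrow(calls),
            nrow(top))

  log_stage("stage anchoring: reading transcript models")
  assembled <- read_gtf(assembled_gtf, source_tag = "assembled")
  annotation <- read_gtf(annotation_gtf, source_tag = "annotated")
  anchored <- anchor_transcripts(assembled, top,
                                 window_nt = config$anchoring$window_nt)
  write_tsv(anchored, file.path(out_dir, "anchored.tsv"))
  cand_ids <- unique(anchored$transcript_id)
  candidates <- Filter(function(m) m$transcript_id %in% cand_ids, assembled)
  log_stage("stage anchoring: %d transcript(s) anchored at %d call(s)",
            length(candidates), nrow(top))

  retained <- flank_filter(candidates, annotation,
                           flank_nt = config$anchoring$flank_nt,
                           antisense_exempt = config$anchoring$antisense_exempt)
  flank_pass <- stats::setNames(
    cand_ids %in% vapply(retained, `[[`, character(1), "transcript_id"),
    cand_ids)

  log_stage("stage coding: scoring %d candidate(s)", length(candidates))
  scorer <- default_coding_model(seed = config$model_seed)
  genome <- read_genome(genome_fa)
  seqs <- vapply(candidates, spliced_sequence, character(1), genome = genome)
  names(seqs) <- vapply(candidates, `[[`, character(1), "transcript_id")
  if (length(seqs) > 0) {
    assessments <- assess_coding(seqs, scorer$hexamer_table)
    assessments$coding_prob <- coding_probability(scorer$model, assessments)
  } else {
    assessments <- data.frame(transcript_id = character(),
                              length_nt = integer(), orf_nt = integer(),
                              orf_start = integer(), orf_coverage = numeric(),
                              fickett = numeric(), hexamer = numeric(),
                              coding_prob = numeric(), stringsAsFactors = FALSE)
  }
  write_tsv(assessments, file.path(out_dir, "assessments.tsv"))
  pfam <- if (!is.null(pfam_tsv)) read_pfam_table(pfam_tsv) else NULL
  ncsc <- if (!is.null(noncoding_tsv)) read_noncoding_scores(noncoding_tsv) else NULL
  decisions <- apply_filter_cascade(assessments, config$cascade,
                                    pfam = pfam, noncoding_scores = ncsc,
                                    flank_pass = flank_pass)

  log_stage("stage expression/classification")
  if (!is.null(counts_tsv)) {
    counts <- read_counts_table(counts_tsv)
    i <- match(assessments$transcript_id, counts$transcript_id)
    rpkm_val <- ifelse(is.na(i), NA_real_,
                       rpkm(counts$count[i], assessments$length_nt,
                            counts$library_size[i]))
  } else {
    rpkm_val <- rep(NA_real_, nrow(assessments))
  }
  classes <- classify_position(candidates, annotation,
                               flank_nt = config$anchoring$flank_nt)

  report <- merge(decisions, classes, by = "transcript_id", all.x = TRUE)
  report$rpkm <- rpkm_val[match(report$transcript_id,
                                assessments$transcript_id)]
  a1 <- anchored[!duplicated(anchored$transcript_id), ]
  report <- merge(report, a1, by = "transcript_id", all.x = TRUE)
  report <- report[order(report$overall != "pass", report$transcript_id), ]
  rownames(report) <- NULL
  write_tsv(report, file.path(out_dir, "report.tsv"))
  log_stage("done: %d candidate(s), %d passing all evaluated criteria",
            nrow(report), sum(report$overall == "pass"))

  invisible(list(calls = calls, top = top, anchored = anchored,
                 assessments = assessments, decisions = decisions,
                 report = report, out_dir = out_dir))
}
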