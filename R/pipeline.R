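#' Run the full analysis pipeline on a synthetic truth set
#'
#' Simulates intensities from the truth set, applies per-sample QC, runs
#' both CNV callers over the kept samples, merges and filters consensus
#' calls, intersects kept deletions with the locus gene intervals, builds
#' censored outcomes for the requested endpoint, runs the genome-wide
#' retrospective-likelihood score test, and attaches discrete-FDR q-values.
#'
#' @param truth a `TruthSet` from [make_truth_set()].
#' @param config a `PipelineConfig`.
#' @param endpoint `"breast"` or `"ovarian"`.
#' @param seed seed for the intensity simulation (default derives from the
#'   truth set's master seed).
#' @return list: `report`, `qc_metrics`, `kept_samples`, `raw_calls`,
#'   `consensus`, `kept_calls`, `removed_calls`, `carrier_matrix`,
#'   `outcomes`, `association` (score-test table with q-values),
#'   `skipped`.
#' @export
run_cnv_pipeline <- function(truth, config = default_pipeline_config(),
                             endpoint = "breast",
                             seed = truth$params$seed + 3L) {
  report <- simulate_intensities(truth$grid, truth,
                                 truth$params$model, seed)
  qc <- compute_cohort_metrics(report, config)
  flt <- filter_samples(qc, config)
  raw <- call_all_samples(report, flt$kept, config)
  cons <- merge_consensus(raw, config)
  kept <- apply_consensus_filters(cons, config)
  genes <- data.frame(symbol = truth$loci$locus,
                      chromosome = truth$loci$chromosome,
                      start = truth$loci$start, end = truth$loci$end,
                      stringsAsFactors = FALSE)
  cm <- intersect_deletions_genes(kept$kept, genes, samples = flt$kept)
  phen <- truth$phenotypes[truth$phenotypes$sample %in% flt$kept, ,
                           drop = FALSE]
  outcomes <- build_outcomes(phen, endpoint)
  gw <- run_genomewide(cm, outcomes, config$incidence[[endpoint]])
  assoc <- gw$results
  if (!is.null(assoc)) {
    fdr <- discrete_fdr(assoc,
                        config$analysis$qvalue_count_threshold,
                        config$analysis$alpha)
    assoc$q <- fdr$q[match(assoc$gene, fdr$gene)]
    assoc$rr_ci <- format_rr_ci(assoc$rr, assoc$ci_lo, assoc$ci_hi)
  }
  list(report = report, qc_metrics = qc, kept_samples = flt$kept,
       raw_calls = raw, consensus = cons, kept_calls = kept$kept,
       removed_calls = kept$removed, carrier_matrix = cm,
       outcomes = outcomes, association = assoc, skipped = gw$skipped)
}
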