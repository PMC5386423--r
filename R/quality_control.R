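.autosome <- function(chrom) {
  !chrom %in% c("chrX", "chrY", "chrM", "chrMT", "X", "Y", "M", "MT")
}

.robust_outlier_rate <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  med <- median(x)
  rsd <- mad(x, center = med) # 1.4826 * MAD
  mean(abs(x - med) > 3 * rsd)
}

# Exclusion rules with the exact strict/inclusive inequality semantics of
# the published criteria; returns the names of the rules that fire.
.qc_failed_rules <- function(m, qc) {
  failed <- character()
  if (m$lrr_sd > qc$max_lrr_sd) failed <- c(failed, "lrr_sd")
  if (m$baf_drift > qc$max_baf_drift) failed <- c(failed, "baf_drift")
  if (abs(m$waviness_factor) > qc$max_waviness)
    failed <- c(failed, "waviness")
  if (m$baf_outlier_rate > qc$max_baf_outlier)
    failed <- c(failed, "baf_outliers")
  if (m$lrr_outlier_rate >= qc$max_lrr_outlier)
    failed <- c(failed, "lrr_outliers")
  if (m$baf_sd >= qc$max_baf_sd) failed <- c(failed, "baf_sd")
  if (m$lrr_sd >= qc$max_lrr_sd_strict) failed <- c(failed, "lrr_sd_strict")
  failed
}

#' Per-sample array quality metrics
#'
#' Computes, over autosomal probes: the s.d. of LRR; the s.d. of BAF
#' restricted to the heterozygous band `[0.25, 0.75]`; BAF drift, the
#' fraction of probes with BAF in the drifted-homozygote band
#' `[0.2, 0.25] U [0.75, 0.8]`; the waviness factor, the s.d. of 1 Mb
#' window medians of LRR signed by the lag-1 autocorrelation of the window
#' medians; and robust outlier rates, the fraction of values beyond 3
#' robust s.d. (1.4826 x MAD) from the sample median, computed separately
#' for LRR (all probes) and BAF (heterozygous band).
#'
#' @param report an [intensity_report()].
#' @param sample sample name.
#' @param config a `PipelineConfig` (thresholds and band definitions).
#' @return one-row `data.frame` with the metrics, `pass`, and
#'   `failed_rules` (comma-separated).
#' @export
compute_sample_metrics <- function(report, sample,
                                   config = default_pipeline_config()) {
  if (!sample %in% report$samples) stop("no such sample: ", sample)
  qc <- config$qc
  auto <- .autosome(report$probes$chromosome)
  lrr <- report$lrr[auto, sample]
  baf <- report$baf[auto, sample]
  pos <- report$probes$position[auto]
  chrom <- report$probes$chromosome[auto]
  usable <- sum(!is.na(lrr) | !is.na(baf))
  if (usable < qc$min_probes)
    stop("insufficient data: ", usable, " usable probes (need >= ",
         qc$min_probes, ")")

  lrr_sd <- sd(lrr, na.rm = TRUE)
  hb <- qc$het_band
  het <- !is.na(baf) & baf >= hb[1] & baf <= hb[2]
  baf_sd <- if (sum(het) >= 2) sd(baf[het]) else 0
  db <- qc$drift_band
  in_drift <- !is.na(baf) &
    ((baf >= db[1] & baf <= db[2]) | (baf >= db[3] & baf <= db[4]))
  baf_drift <- sum(in_drift) / sum(!is.na(baf))

  win <- paste(chrom, pos %/% qc$waviness_window_bp)
  ok <- !is.na(lrr)
  med <- tapply(lrr[ok], factor(win[ok], levels = unique(win[ok])), median)
  # partial windows at chromosome ends carry almost no averaging and would
  # dominate the spread; require a minimal marker count per window
  cnt <- tapply(rep(1, sum(ok)), factor(win[ok], levels = unique(win[ok])),
                sum)
  med <- med[cnt >= 10]
  if (length(med) >= 2) {
    wf_mag <- sd(med)
    ac <- if (length(med) >= 3)
      acf(as.numeric(med), lag.max = 1, plot = FALSE)$acf[2] else 1
    waviness <- wf_mag * sign(ifelse(is.na(ac) || ac == 0, 1, ac))
  } else waviness <- 0

  lrr_outlier <- .robust_outlier_rate(lrr)
  baf_outlier <- .robust_outlier_rate(baf[het])
  if (is.na(baf_outlier)) baf_outlier <- 0

  m <- data.frame(sample = sample, lrr_sd = lrr_sd, baf_sd = baf_sd,
                  baf_drift = baf_drift, waviness_factor = waviness,
                  baf_outlier_rate = baf_outlier,
                  lrr_outlier_rate = lrr_outlier,
                  stringsAsFactors = FALSE)
  failed <- .qc_failed_rules(m, qc)
  m$pass <- length(failed) == 0
  m$failed_rules <- paste(failed, collapse = ",")
  m
}

#' QC metrics for every sample in a report
#' @inheritParams compute_sample_metrics
#' @return `data.frame`, one row per sample.
#' @export
compute_cohort_metrics <- function(report,
                                   config = default_pipeline_config()) {
  out <- lapply(report$samples, compute_sample_metrics,
                report = report, config = config)
  do.call(rbind, out)
}

#' Apply sample-exclusion thresholds
#'
#' A sample is excluded if any rule fires: LRR s.d. > 0.28, BAF drift
#' > 0.01, |waviness factor| > 0.05, BAF outliers > 0.1, LRR outliers
#' >= 0.1, BAF s.d. >= 0.2, LRR s.d. >= 0.4.  Strict versus inclusive
#' inequalities follow the published exclusion criteria exactly.  The rules
#' are re-evaluated from the metric columns, so the function also accepts
#' externally assembled metric tables.
#'
#' @param metrics `data.frame` from [compute_cohort_metrics()].
#' @param config a `PipelineConfig`.
#' @return list with `kept` (character sample names) and `excluded`
#'   (metric rows of excluded samples, with `failed_rules` filled in).
#' @export
filter_samples <- function(metrics, config = default_pipeline_config()) {
  rules <- lapply(seq_len(nrow(metrics)), function(i)
    .qc_failed_rules(metrics[i, ], config$qc))
  keep <- lengths(rules) == 0
  excluded <- metrics[!keep, , drop = FALSE]
  excluded$failed_rules <- vapply(rules[!keep], paste, "", collapse = ",")
  excluded$pass <- rep(FALSE, nrow(excluded))
  list(kept = metrics$sample[keep], excluded = excluded)
}
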