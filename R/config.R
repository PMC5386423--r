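#' Piecewise-constant baseline incidence model
#'
#' Age-specific baseline hazards for a cancer endpoint, represented as
#' contiguous age bands `[age_start, age_end)` with a constant annual hazard
#' in each band.  Bands must start at age 0, be contiguous and
#' non-overlapping; beyond the last band the final hazard is extended
#' indefinitely.
#'
#' @param age_start,age_end numeric vectors of band boundaries in years.
#' @param hazard non-negative annual hazards, one per band.
#' @param endpoint `"breast"` or `"ovarian"`.
#' @return A `data.frame` of class `IncidenceModel` with columns
#'   `age_start`, `age_end`, `hazard` and an `endpoint` attribute.
#' @export
incidence_model <- function(age_start, age_end, hazard,
                            endpoint = c("breast", "ovarian")) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(age_start) == length(age_end),
            length(age_start) == length(hazard))
  if (age_start[1] != 0)
    stop("incidence age bands must start at age 0")
  if (any(age_end <= age_start))
    stop("incidence age bands must have age_end > age_start")
  if (length(age_start) > 1 &&
      any(abs(age_start[-1] - age_end[-length(age_end)]) > 1e-9))
    stop("incidence age bands must be contiguous and non-overlapping")
  if (any(hazard < 0)) stop("hazards must be >= 0")
  out <- data.frame(age_start = as.numeric(age_start),
                    age_end = as.numeric(age_end),
                    hazard = as.numeric(hazard))
  attr(out, "endpoint") <- endpoint
  class(out) <- c("IncidenceModel", "data.frame")
  out
}

#' Default baseline incidence for BRCA1 pathogenic-variant carriers
#'
#' Decade-wise annual hazards chosen so that the cumulative risks sit near
#' the upper end of published penetrance estimates for BRCA1 carriers from
#' case-enriched families (~75% breast and ~45% ovarian cancer by age 70).
#' These are the defaults used by the synthetic-data generator and the test
#' suite; they are configuration, not estimates from any particular cohort.
#'
#' @param endpoint `"breast"` or `"ovarian"`.
#' @return An [incidence_model()].
#' @export
default_incidence <- function(endpoint = c("breast", "ovarian")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "breast") {
    incidence_model(age_start = c(0, 20, 30, 40, 50, 60),
                    age_end   = c(20, 30, 40, 50, 60, 70),
                    hazard    = c(0, 0.010, 0.028, 0.035, 0.033, 0.033),
                    endpoint  = "breast")
  } else {
    incidence_model(age_start = c(0, 30, 40, 50, 60),
                    age_end   = c(30, 40, 50, 60, 70),
                    hazard    = c(0, 0.004, 0.015, 0.020, 0.021),
                    endpoint  = "ovarian")
  }
}

#' Default pipeline configuration
#'
#' Bundles every tunable of the pipeline: per-sample QC thresholds (with the
#' exact strict/inclusive inequality semantics used for exclusion), HMM and
#' segmentation caller parameters, consensus merge/filter rules (minimum
#' caller support, maximum event length, the MHC conflict region), baseline
#' incidence tables for both endpoints, and analysis options (carrier
#' frequency convention, minimum deletion count retained for q-values).
#'
#' @return A nested list of class `PipelineConfig`.
#' @export
default_pipeline_config <- function() {
  cfg <- list(
    qc = list(
      max_lrr_sd = 0.28,            # strict >
      max_baf_drift = 0.01,         # strict >
      max_waviness = 0.05,          # strict > on |waviness factor|
      max_baf_outlier = 0.1,        # strict >
      max_lrr_outlier = 0.1,        # inclusive >=
      max_baf_sd = 0.2,             # inclusive >=
      max_lrr_sd_strict = 0.4,      # inclusive >=
      drift_band = c(0.20, 0.25, 0.75, 0.80),
      het_band = c(0.25, 0.75),
      waviness_window_bp = 1e6,
      min_probes = 100
    ),
    hmm = list(
      lrr_means = c(-3.5, -0.66, 0, 0.40, 0.68),
      lrr_sd = 0.20,
      baf_sd = 0.05,
      p_event = 0.01,
      dist_scale_bp = 1e5,
      min_probes = 3
    ),
    seg = list(
      t_threshold = 5,
      min_probes = 3,
      max_seg_probes = 120,
      del_threshold = -0.3,
      hom_del_threshold = -2.0,
      dup_threshold = 0.25
    ),
    consensus = list(
      min_support = 2,
      max_length_bp = 1e6,
      mhc_chromosome = "chr6",
      mhc_start = 29600000,
      mhc_end = 33100000
    ),
    incidence = list(breast = default_incidence("breast"),
                     ovarian = default_incidence("ovarian")),
    analysis = list(
      frequency = "carrier",
      qvalue_count_threshold = 4,
      alpha = 0.05
    )
  )
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config a `PipelineConfig`.
#' @param path output file path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  ser$incidence <- lapply(ser$incidence, function(m)
    list(age_start = m$age_start, age_end = m$age_end, hazard = m$hazard,
         endpoint = attr(m, "endpoint")))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return A validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$incidence <- lapply(raw$incidence, function(m)
    incidence_model(m$age_start, m$age_end, m$hazard, m$endpoint))
  for (fld in c("qc", "hmm", "seg", "consensus", "analysis"))
    if (is.null(raw[[fld]])) stop("config missing section: ", fld)
  if (raw$consensus$min_support < 1) stop("min_support must be >= 1")
  class(raw) <- c("PipelineConfig", "list")
  raw
}
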