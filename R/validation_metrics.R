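#' Round to nearest integer, halves away from zero
#'
#' The rounding convention for reported percentages (14/22 -> 64%,
#' 8/29 -> 28%, 7/352 -> 2%, 9/52 -> 17%, 13/72 -> 18%).
#'
#' @param x numeric.
#' @return numeric of the same length.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.overlaps1 <- function(s1, e1, s2, e2) pmax(s1, s2) <= pmin(e1, e2)

#' Truth-comparison summary from counts
#'
#' @param n_confirmed calls confirmed by truth (equivalently, truth
#'   segments detected when calls and truths pair one-to-one).
#' @param n_unconfirmed calls with no truth support.
#' @param n_missed truth segments with no call.
#' @return list of class `TruthComparison` with `sensitivity` and
#'   `specificity` fractions and rounded percentages.  Sensitivity is
#'   detected / (detected + missed); "specificity" is the fraction of
#'   calls confirmed (positive predictive value: true negatives are not
#'   countable in this design).  Either is `NA` when its denominator is 0.
#' @export
truth_comparison <- function(n_confirmed, n_unconfirmed, n_missed) {
  sens_den <- n_confirmed + n_missed
  spec_den <- n_confirmed + n_unconfirmed
  sens <- if (sens_den > 0) n_confirmed / sens_den else NA_real_
  spec <- if (spec_den > 0) n_confirmed / spec_den else NA_real_
  structure(list(n_called_confirmed = n_confirmed,
                 n_called_unconfirmed = n_unconfirmed,
                 n_truth_missed = n_missed,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = round_half_up(100 * sens),
                 specificity_pct = round_half_up(100 * spec)),
            class = "TruthComparison")
}

#' Detection sensitivity and specificity at a locus
#'
#' Restricts truth segments and kept consensus deletions to those
#' overlapping the locus by at least 1 bp; a truth segment is detected if a
#' same-sample deletion call overlaps it, and a call is confirmed if it
#' overlaps a same-sample truth segment.
#'
#' @param called consensus `data.frame` (kept deletions).
#' @param truth_segments `data.frame` with `sample`, `chromosome`,
#'   `start`, `end`.
#' @param locus one-row `data.frame` or list with `chromosome`, `start`,
#'   `end`.
#' @return a [truth_comparison()], plus per-segment detail in
#'   `attr(, "detail")`.
#' @export
locus_detection_metrics <- function(called, truth_segments, locus) {
  tr <- truth_segments[truth_segments$chromosome == locus$chromosome &
                         .overlaps1(truth_segments$start, truth_segments$end,
                                    locus$start, locus$end), , drop = FALSE]
  ca <- called[called$direction == "deletion" &
                 called$chromosome == locus$chromosome &
                 .overlaps1(called$start, called$end,
                            locus$start, locus$end), , drop = FALSE]
  detected <- vapply(seq_len(nrow(tr)), function(i) {
    any(ca$sample == tr$sample[i] &
          .overlaps1(ca$start, ca$end, tr$start[i], tr$end[i]))
  }, logical(1))
  confirmed <- vapply(seq_len(nrow(ca)), function(i) {
    any(tr$sample == ca$sample[i] &
          .overlaps1(tr$start, tr$end, ca$start[i], ca$end[i]))
  }, logical(1))
  out <- truth_comparison(n_confirmed = sum(confirmed),
                          n_unconfirmed = sum(!confirmed),
                          n_missed = sum(!detected))
  attr(out, "detail") <- list(truth = cbind(tr, detected = detected),
                              calls = cbind(ca, confirmed = confirmed))
  out
}

#' Validation rate over attempted loci
#'
#' @param attempted character vector of locus names taken to validation.
#' @param confirmed subset of `attempted` that validated.
#' @return percentage, rounded to the nearest integer (half away from
#'   zero).
#' @export
validation_rate <- function(attempted, confirmed) {
  if (length(attempted) == 0) stop("no attempted loci")
  if (length(setdiff(confirmed, attempted)) > 0)
    stop("confirmed loci must be a subset of attempted loci")
  round_half_up(100 * length(confirmed) / length(attempted))
}

#' False-negative rate of the bioinformatic calls
#'
#' @param assay_positive_call_negative loci positive by assay but negative
#'   by calling.
#' @param call_negative_total all call-negative assessments.
#' @return percentage, rounded to the nearest integer.
#' @export
false_negative_rate <- function(assay_positive_call_negative,
                                call_negative_total) {
  if (call_negative_total <= 0) stop("denominator must be > 0")
  round_half_up(100 * assay_positive_call_negative / call_negative_total)
}

#' Concordance with an external CNV map
#'
#' Flags each locus as present on the map if any map region overlaps it by
#' at least 1 bp, and summarizes the on-map percentage.
#'
#' @param loci gene-interval `data.frame` (`symbol`, `chromosome`,
#'   `start`, `end`).
#' @param map_regions interval `data.frame` (`chromosome`, `start`,
#'   `end`).
#' @return list with `on_map` (named logical) and `pct` (rounded
#'   percentage; 0 when the map is empty).
#' @export
map_concordance <- function(loci, map_regions) {
  on_map <- vapply(seq_len(nrow(loci)), function(i) {
    nrow(map_regions) > 0 &&
      any(map_regions$chromosome == loci$chromosome[i] &
            .overlaps1(map_regions$start, map_regions$end,
                       loci$start[i], loci$end[i]))
  }, logical(1))
  names(on_map) <- loci$symbol
  pct <- if (nrow(loci) > 0) round_half_up(100 * mean(on_map)) else NA_real_
  list(on_map = on_map, pct = pct)
}
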