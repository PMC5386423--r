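.empty_calls <- function() {
  data.frame(sample = character(), chromosome = character(),
             start = integer(), end = integer(), state = integer(),
             n_probes = integer(), confidence = numeric(),
             caller = character(), stringsAsFactors = FALSE)
}

#' HMM copy-number caller
#'
#' Five-state (copy number 0–4) hidden Markov model over the ordered probes
#' of each chromosome.  Emissions sum an LRR term, Normal around the
#' per-state mean, and a BAF term, an equal-weight mixture over the
#' genotype clusters implied by the state (copy 1: \{0, 1\}; copy 2:
#' \{0, 1/2, 1\}; copy 3: \{0, 1/3, 2/3, 1\}; copy 0: uniform).  Transition
#' stay probability is `1 - p_event * (1 - exp(-d / D))` for inter-probe
#' distance `d` and scale `D`, off-diagonal mass split evenly.  Maximal
#' non-diploid runs of the Viterbi path with at least `min_probes` probes
#' become calls; the confidence is the log-likelihood of the decoded run
#' minus the all-diploid alternative over the same probes (emissions plus
#' within-run transitions).
#'
#' @param report an [intensity_report()].
#' @param sample sample name.
#' @param config a `PipelineConfig`; `config$hmm` holds the parameters.
#' @return `data.frame` of calls (`sample`, `chromosome`, `start`, `end`,
#'   `state`, `n_probes`, `confidence`, `caller`).
#' @export
call_hmm <- function(report, sample, config = default_pipeline_config()) {
  if (!sample %in% report$samples) stop("no such sample: ", sample)
  hp <- config$hmm
  sds <- rep_len(hp$lrr_sd, 5)
  out <- list()
  for (chr in unique(report$probes$chromosome)) {
    idx <- which(report$probes$chromosome == chr)
    if (length(idx) < hp$min_probes) next
    pos <- report$probes$position[idx]
    vit <- viterbi_cnv(report$lrr[idx, sample], report$baf[idx, sample],
                       pos, hp$lrr_means, sds, hp$baf_sd,
                       hp$p_event, hp$dist_scale_bp)
    states <- vit$states
    em <- vit$logemit
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      st <- r$values[k]
      if (st == 2L || r$lengths[k] < hp$min_probes) next
      i1 <- starts[k]; i2 <- ends[k]
      run <- i1:i2
      d <- diff(pos[run])
      theta <- hp$p_event * (1 - exp(-d / hp$dist_scale_bp))
      ll_path <- sum(em[cbind(run, states[run] + 1L)]) +
        sum(log(1 - theta))
      ll_dip <- sum(em[run, 3]) + sum(log(1 - theta))
      out[[length(out) + 1]] <- data.frame(
        sample = sample, chromosome = chr,
        start = pos[i1], end = pos[i2], state = st,
        n_probes = r$lengths[k], confidence = ll_path - ll_dip,
        caller = "hmm", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(.empty_calls())
  do.call(rbind, out)
}

# Two-sample pooled-variance t statistics for every split of x at
# k = min_probes..(n - min_probes); vectorized via cumulative sums.
.split_tstats <- function(x, min_probes) {
  n <- length(x)
  k <- seq(min_probes, n - min_probes)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  ss1 <- cs2[k] - k * m1^2
  ss2 <- (cs2[n] - cs2[k]) - (n - k) * m2^2
  sp2 <- pmax(ss1 + ss2, 0) / (n - 2)
  se <- sqrt(sp2 * (1 / k + 1 / (n - k)))
  t <- (m1 - m2) / se
  t[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 0,
                       sign(m1[se == 0] - m2[se == 0]) * Inf)
  list(k = k, t = t)
}

#' Binary-segmentation copy-number caller
#'
#' Recursive binary segmentation of the LRR signal per chromosome: each
#' segment is split at the position maximizing the absolute two-sample t
#' statistic; a split is accepted if |t| exceeds `t_threshold` and both
#' sides keep at least `min_probes` probes.  A single chromosome-scale
#' split cannot expose a short interior event (its t statistic is diluted
#' by the flanking diploid signal), so segments longer than
#' `max_seg_probes` are always split at the maximizing position and the
#' threshold decision is made at that scale; spurious forced boundaries
#' are removed afterwards because adjacent same-state segments are
#' re-merged.  Final segments are classified by mean LRR: below
#' `hom_del_threshold` copy 0, below `del_threshold` copy 1, above
#' `dup_threshold` copy 3, otherwise diploid (no call).  The confidence
#' reported is the one-sample |t| of the segment mean against 0.
#'
#' @inheritParams call_hmm
#' @return `data.frame` of calls, as [call_hmm()].
#' @export
call_segmentation <- function(report, sample,
                              config = default_pipeline_config()) {
  if (!sample %in% report$samples) stop("no such sample: ", sample)
  sp <- config$seg
  out <- list()
  for (chr in unique(report$probes$chromosome)) {
    idx <- which(report$probes$chromosome == chr &
                   !is.na(report$lrr[, sample]))
    if (length(idx) < sp$min_probes) next
    x <- report$lrr[idx, sample]
    pos <- report$probes$position[idx]
    leaves <- list()
    segment <- function(lo, hi) {
      n <- hi - lo + 1
      if (n >= 2 * sp$min_probes) {
        ts <- .split_tstats(x[lo:hi], sp$min_probes)
        best <- which.max(abs(ts$t))
        if (length(best) == 1 &&
            (abs(ts$t[best]) > sp$t_threshold || n > sp$max_seg_probes)) {
          k <- ts$k[best]
          segment(lo, lo + k - 1)
          segment(lo + k, hi)
          return(invisible())
        }
      }
      leaves[[length(leaves) + 1]] <<- c(lo, hi)
      invisible()
    }
    segment(1, length(x))
    # classify leaves, then merge adjacent leaves with equal state
    st <- vapply(leaves, function(b) {
      m <- mean(x[b[1]:b[2]])
      if (m < sp$hom_del_threshold) 0L
      else if (m < sp$del_threshold) 1L
      else if (m > sp$dup_threshold) 3L
      else 2L
    }, integer(1))
    ord <- order(vapply(leaves, `[`, numeric(1), 1))
    leaves <- leaves[ord]; st <- st[ord]
    r <- rle(st)
    hi_i <- cumsum(r$lengths)
    lo_i <- hi_i - r$lengths + 1
    for (k in seq_along(r$values)) {
      s <- r$values[k]
      if (s == 2L) next
      i1 <- leaves[[lo_i[k]]][1]; i2 <- leaves[[hi_i[k]]][2]
      n <- i2 - i1 + 1
      if (n < sp$min_probes) next
      seg_x <- x[i1:i2]
      conf <- if (n >= 2 && sd(seg_x) > 0)
        abs(mean(seg_x)) / (sd(seg_x) / sqrt(n)) else Inf
      out[[length(out) + 1]] <- data.frame(
        sample = sample, chromosome = chr,
        start = pos[i1], end = pos[i2], state = s, n_probes = n,
        confidence = conf, caller = "seg", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(.empty_calls())
  do.call(rbind, out)
}

#' Merge per-caller calls into consensus calls
#'
#' Within each sample and direction (deletion: state < 2; duplication:
#' state > 2), calls overlapping by at least 1 bp are grouped transitively;
#' each group becomes one consensus call spanning the union interval, with
#' support equal to the number of distinct callers contributing.
#'
#' @param calls `data.frame` of calls from one or more callers.
#' @param config a `PipelineConfig`.
#' @return consensus `data.frame`: `sample`, `chromosome`, `start`, `end`,
#'   `direction`, `support`, `callers` (comma-joined), `n_members`.
#' @export
merge_consensus <- function(calls, config = default_pipeline_config()) {
  empty <- data.frame(sample = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      direction = character(), support = integer(),
                      callers = character(), n_members = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  calls$direction <- ifelse(calls$state < 2, "deletion", "duplication")
  out <- list()
  for (key in unique(paste(calls$sample, calls$direction, calls$chromosome))) {
    sub <- calls[paste(calls$sample, calls$direction,
                       calls$chromosome) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L; grp[1] <- 1L
    maxend <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] > maxend) g <- g + 1L
      grp[i] <- g
      maxend <- max(maxend, sub$end[i])
    }
    for (gi in seq_len(g)) {
      m <- sub[grp == gi, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        sample = m$sample[1], chromosome = m$chromosome[1],
        start = min(m$start), end = max(m$end),
        direction = m$direction[1],
        support = length(unique(m$caller)),
        callers = paste(sort(unique(m$caller)), collapse = ","),
        n_members = nrow(m), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consensus-level exclusion filters
#'
#' Removes consensus calls whose union interval is at least `max_length_bp`
#' long (length computed 1-based inclusive, `end - start + 1`), calls
#' supported by fewer than `min_support` callers, and, within the
#' configured MHC interval, deletion/duplication pairs of the same sample
#' that each retain the required support (mutually contradictory calls).
#'
#' @param calls consensus `data.frame` from [merge_consensus()].
#' @param config a `PipelineConfig`.
#' @return list with `kept` and `removed` (with a `reason` column).
#' @export
apply_consensus_filters <- function(calls,
                                    config = default_pipeline_config()) {
  cc <- config$consensus
  reason <- rep(NA_character_, nrow(calls))
  len <- calls$end - calls$start + 1
  reason[len >= cc$max_length_bp] <- "length>=max_length_bp"
  low <- is.na(reason) & calls$support < cc$min_support
  reason[low] <- "support<min_support"
  in_mhc <- calls$chromosome == cc$mhc_chromosome &
    calls$start <= cc$mhc_end & calls$end >= cc$mhc_start
  for (s in unique(calls$sample)) {
    cand <- is.na(reason) & in_mhc & calls$sample == s &
      calls$support >= cc$min_support
    if (any(calls$direction[cand] == "deletion") &&
        any(calls$direction[cand] == "duplication"))
      reason[cand] <- "mhc_del_dup_conflict"
  }
  list(kept = calls[is.na(reason), , drop = FALSE],
       removed = cbind(calls[!is.na(reason), , drop = FALSE],
                       reason = reason[!is.na(reason)]))
}

#' Run both callers over the kept samples
#'
#' @param report an [intensity_report()].
#' @param samples sample names that passed QC.
#' @param config a `PipelineConfig`.
#' @return combined call `data.frame` from [call_hmm()] and
#'   [call_segmentation()].
#' @export
call_all_samples <- function(report, samples,
                             config = default_pipeline_config()) {
  out <- lapply(samples, function(s)
    rbind(call_hmm(report, s, config),
          call_segmentation(report, s, config)))
  res <- do.call(rbind, out)
  if (is.null(res)) .empty_calls() else res
}
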