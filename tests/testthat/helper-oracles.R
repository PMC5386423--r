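# Independent oracles and fixture builders used across the suite.  These
# deliberately re-derive quantities with naive code (enumeration, quadratic
# scans) so the package implementations are checked against something that
# shares none of their machinery.

# --- HMM oracle ------------------------------------------------------------

.oracle_baf_clusters <- list(`0` = NULL, `1` = c(0, 1), `2` = c(0, 0.5, 1),
                             `3` = c(0, 1 / 3, 2 / 3, 1),
                             `4` = c(0, 0.25, 0.5, 0.75, 1))

oracle_log_emissions <- function(lrr, baf, means, sds, baf_sd) {
  n <- length(lrr)
  em <- matrix(0, n, 5)
  for (s in 0:4) {
    le <- rep(0, n)
    ok <- !is.na(lrr)
    le[ok] <- dnorm(lrr[ok], means[s + 1], sds[s + 1], log = TRUE)
    cl <- .oracle_baf_clusters[[as.character(s)]]
    okb <- !is.na(baf)
    if (!is.null(cl)) {
      dens <- rowMeans(vapply(cl, function(c0) dnorm(baf[okb], c0, baf_sd),
                              numeric(sum(okb))))
      le[okb] <- le[okb] + log(dens)
    }
    em[, s + 1] <- le
  }
  em
}

# Exhaustive maximum-likelihood state path over all 5^n paths.
oracle_best_path <- function(lrr, baf, pos, hp) {
  n <- length(lrr)
  stopifnot(n <= 8)
  em <- oracle_log_emissions(lrr, baf, hp$lrr_means,
                             rep_len(hp$lrr_sd, 5), hp$baf_sd)
  grid <- as.matrix(expand.grid(rep(list(0:4), n)))
  prior <- log(c(rep(hp$p_event / 4, 2), 1 - hp$p_event,
                 rep(hp$p_event / 4, 2)))
  ll <- prior[grid[, 1] + 1]
  for (j in 1:n) ll <- ll + em[cbind(j, grid[, j] + 1)]
  if (n > 1) {
    for (j in 2:n) {
      d <- pos[j] - pos[j - 1]
      theta <- hp$p_event * (1 - exp(-d / hp$dist_scale_bp))
      stay <- grid[, j] == grid[, j - 1]
      ll <- ll + ifelse(stay, log(1 - theta), log(theta / 4))
    }
  }
  as.integer(grid[which.max(ll), ])
}

# --- interval oracles ------------------------------------------------------

oracle_overlap_matrix <- function(calls, genes, samples) {
  z <- matrix(0L, length(samples), nrow(genes),
              dimnames = list(samples, genes$symbol))
  for (i in seq_len(nrow(calls))) {
    if (calls$direction[i] != "deletion") next
    for (j in seq_len(nrow(genes))) {
      if (calls$chromosome[i] == genes$chromosome[j] &&
          max(calls$start[i], genes$start[j]) <=
            min(calls$end[i], genes$end[j]))
        z[calls$sample[i], genes$symbol[j]] <- 1L
    }
  }
  z
}

# Connected components of the pairwise >=1 bp overlap graph.
oracle_overlap_groups <- function(starts, ends) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && max(starts[i], starts[j]) <= min(ends[i], ends[j]) &&
          grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# --- fixture builders ------------------------------------------------------

flat_report <- function(n = 200, samples = "S1", spacing = 5000,
                        chromosome = "chr1", lrr = 0, baf = 0.5) {
  probes <- data.frame(probe_id = sprintf("%s_p%04d", chromosome, 1:n),
                       chromosome = chromosome,
                       position = seq_len(n) * spacing)
  lrr_m <- matrix(lrr, n, length(samples),
                  dimnames = list(NULL, samples))
  baf_m <- matrix(baf, n, length(samples),
                  dimnames = list(NULL, samples))
  intensity_report(probes, lrr_m, baf_m)
}

# phenotype rows with all-optional event ages
pheno_row <- function(sample = "P1", bc = NA, oc = NA, mast = NA,
                      ooph = NA, last = 60) {
  data.frame(sample = sample, age_bc_dx = bc, age_oc_dx = oc,
             age_mastectomy = mast, age_oophorectomy = ooph,
             age_last_obs = last, stringsAsFactors = FALSE)
}

# 20-record association fixture with a moderate positive association
assoc_fixture <- function() {
  list(
    t = c(35, 40, 52, 38, 60, 45, 55, 33, 47, 50,
          62, 28, 39, 44, 58, 36, 49, 53, 41, 66),
    delta = c(1, 0, 1, 0, 0, 1, 0, 1, 0, 1,
              0, 1, 0, 1, 0, 0, 1, 0, 1, 0),
    z = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1,
          0, 0, 1, 0, 0, 0, 1, 0, 0, 0)
  )
}
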