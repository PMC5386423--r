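#' Cumulative baseline hazard
#'
#' `Lambda0(t)` for a piecewise-constant [incidence_model()]: the hazard
#' integrated over `[0, t)`.  Beyond the last age band the final hazard is
#' extended.
#'
#' @param model an [incidence_model()].
#' @param t vector of ages (years), `t >= 0`.
#' @return numeric vector of cumulative hazards.
#' @export
cumulative_hazard <- function(model, t) {
  stopifnot(all(t >= 0))
  K <- nrow(model)
  vapply(t, function(ti) {
    width <- pmin(ti, model$age_end) - pmin(ti, model$age_start)
    extra <- max(0, ti - model$age_end[K]) * model$hazard[K]
    sum(model$hazard * width) + extra
  }, numeric(1))
}

.hazard_at <- function(model, t) {
  K <- nrow(model)
  k <- findInterval(t, model$age_start)
  k[k < 1] <- 1
  k[t >= model$age_end[K]] <- K
  model$hazard[k]
}

#' Build analysis outcomes from carrier phenotypes
#'
#' Breast endpoint: a carrier is classified at the age of first breast
#' cancer diagnosis, or censored at ovarian cancer diagnosis or bilateral
#' prophylactic mastectomy, whichever occurred first, or at the age of last
#' observation; only breast cancer counts as affected.  Ovarian endpoint:
#' classified at ovarian cancer diagnosis, or censored at bilateral
#' prophylactic oophorectomy or age at last observation, with breast-cancer
#' cases treated as unaffected at their breast cancer diagnosis age.
#'
#' @param phenos validated phenotype `data.frame` (see
#'   [read_phenotype_table()]).
#' @param endpoint `"breast"` or `"ovarian"`.
#' @return `data.frame` with `sample`, `t`, `delta`, `endpoint`.
#' @export
build_outcomes <- function(phenos, endpoint = c("breast", "ovarian")) {
  endpoint <- match.arg(endpoint)
  phenos <- validate_phenotypes(phenos)
  if (endpoint == "breast") {
    t <- pmin(phenos$age_bc_dx, phenos$age_oc_dx, phenos$age_mastectomy,
              phenos$age_last_obs, na.rm = TRUE)
    delta <- as.integer(!is.na(phenos$age_bc_dx) & phenos$age_bc_dx <= t)
  } else {
    t <- pmin(phenos$age_oc_dx, phenos$age_oophorectomy, phenos$age_bc_dx,
              phenos$age_last_obs, na.rm = TRUE)
    delta <- as.integer(!is.na(phenos$age_oc_dx) & phenos$age_oc_dx <= t)
  }
  data.frame(sample = phenos$sample, t = t, delta = delta,
             endpoint = endpoint, stringsAsFactors = FALSE)
}

#' Retrospective log-likelihood of carrier status given phenotype
#'
#' The log-likelihood of observing the carrier indicators conditional on
#' the observed phenotypes under hazard `lambda0(t) * exp(beta * z)` and
#' carrier probability `p`:
#' `sum_i log P(z_i | delta_i, t_i)` with
#' `P(delta = 1, t | z) = lambda0(t) e^{beta z} exp(-Lambda0(t) e^{beta z})`
#' and `P(delta = 0, t | z) = exp(-Lambda0(t) e^{beta z})`.  This is the
#' appropriate likelihood when sampling is outcome-dependent, as in a
#' case-enriched carrier cohort.
#'
#' @param beta log relative risk.
#' @param z binary carrier vector.
#' @param t,delta analysis ages and affected indicators.
#' @param model an [incidence_model()].
#' @param p carrier probability; defaults to the null MLE `mean(z)`.
#' @return scalar log-likelihood.
#' @export
retrospective_loglik <- function(beta, z, t, delta, model, p = mean(z)) {
  Lam <- cumulative_hazard(model, t)
  lam <- .hazard_at(model, t)
  logf <- function(zz) {
    ifelse(delta == 1, log(lam) + beta * zz, 0) - Lam * exp(beta * zz)
  }
  l1 <- logf(1) + log(p)
  l0 <- logf(0) + log(1 - p)
  lmax <- pmax(l0, l1)
  denom <- lmax + log(exp(l0 - lmax) + exp(l1 - lmax))
  sum(ifelse(z == 1, l1, l0) - denom)
}

#' Retrospective-likelihood 1 d.f. score test
#'
#' Score test of `H0: beta = 0` in the model with hazard
#' `lambda0(t) * exp(beta * z)` under the retrospective likelihood, with
#' the carrier probability plugged in at its null MLE `p = mean(z)`:
#' `U = sum_i (z_i - p) w_i` with `w_i = delta_i - Lambda0(t_i)`.
#' Because `p` is estimated, the null variance of `U` is that of the
#' efficient score, `V = p (1 - p) sum_i (w_i - mean(w))^2` (centering `w`
#' leaves `U` itself unchanged since the `z_i - p` sum to zero);
#' `chisq = U^2 / V` is referred to chi-square on 1 d.f.  The approximate
#' relative risk is the one-step estimate `exp(U / V)` with 95% CI
#' `exp(U / V +/- 1.96 / sqrt(V))`.
#'
#' @param outcomes `data.frame` from [build_outcomes()].
#' @param z binary carrier vector aligned with `outcomes`.
#' @param model the [incidence_model()] for the endpoint.
#' @return one-row `data.frame`: `n`, `carriers`, `carrier_freq`, `U`,
#'   `V`, `chisq`, `p`, `beta_hat`, `rr`, `ci_lo`, `ci_hi`, `degenerate`.
#' @export
score_test <- function(outcomes, z, model) {
  stopifnot(nrow(outcomes) == length(z), nrow(outcomes) >= 2,
            all(z %in% c(0, 1)))
  phat <- mean(z)
  w <- outcomes$delta - cumulative_hazard(model, outcomes$t)
  U <- sum((z - phat) * w)
  V <- phat * (1 - phat) * sum((w - mean(w))^2)
  if (V <= 0) {
    return(data.frame(n = length(z), carriers = sum(z),
                      carrier_freq = phat, U = U, V = V, chisq = 0,
                      p = 1, beta_hat = NA_real_, rr = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      degenerate = TRUE))
  }
  chisq <- U^2 / V
  beta_hat <- U / V
  data.frame(n = length(z), carriers = sum(z), carrier_freq = phat,
             U = U, V = V, chisq = chisq,
             p = pchisq(chisq, df = 1, lower.tail = FALSE),
             beta_hat = beta_hat, rr = exp(beta_hat),
             ci_lo = exp(beta_hat - 1.96 / sqrt(V)),
             ci_hi = exp(beta_hat + 1.96 / sqrt(V)),
             degenerate = FALSE)
}

#' Genome-wide per-gene score tests
#'
#' One score test per gene of the carrier matrix with at least one carrier;
#' genes with zero carriers (or all carriers) are skipped with a reason.
#' Gene order follows the matrix columns.
#'
#' @param matrix a `CarrierMatrix` from [intersect_deletions_genes()].
#' @param outcomes `data.frame` from [build_outcomes()]; must cover every
#'   matrix sample.
#' @param model the [incidence_model()] for the endpoint.
#' @return list with `results` (per-gene `data.frame`, including
#'   `n_deletions`) and `skipped` (`gene`, `reason`).
#' @export
run_genomewide <- function(matrix, outcomes, model) {
  missing_s <- setdiff(matrix$samples, outcomes$sample)
  if (length(missing_s) > 0)
    stop("samples without outcomes: ", paste(missing_s, collapse = ", "))
  oc <- outcomes[match(matrix$samples, outcomes$sample), , drop = FALSE]
  results <- list()
  skipped <- list()
  for (g in colnames(matrix$z)) {
    zg <- matrix$z[, g]
    if (sum(zg) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(gene = g, reason = "no carriers")
      next
    }
    if (all(zg == 1)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(gene = g, reason = "all carriers")
      next
    }
    res <- score_test(oc, zg, model)
    res <- cbind(gene = g, res, allele_freq = sum(zg) / (2 * length(zg)),
                 n_deletions = as.integer(matrix$deletion_count[[g]]))
    results[[length(results) + 1]] <- res
  }
  list(results = if (length(results)) do.call(rbind, results) else NULL,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(gene = character(), reason = character()))
}

#' Discrete-statistic q-values with a deletion-count filter
#'
#' Genes whose total deletion count is below `count_threshold` cannot reach
#' small p-values under the discrete null and are excluded from the
#' multiplicity correction (flagged `filtered`, q-value missing).
#' Benjamini–Hochberg step-up q-values are computed on the retained set.
#'
#' @param results per-gene `data.frame` with `gene`, `p`, `n_deletions`.
#' @param count_threshold minimum deletion count retained (default 4).
#' @param alpha nominal FDR level carried along for reporting.
#' @return `data.frame` with `gene`, `p`, `n_deletions`, `retained`, `q`.
#' @export
discrete_fdr <- function(results, count_threshold = 4, alpha = 0.05) {
  retained <- results$n_deletions >= count_threshold
  q <- rep(NA_real_, nrow(results))
  if (any(retained)) {
    q[retained] <- p.adjust(results$p[retained], method = "BH")
  } else {
    warning("no genes retained by the deletion-count filter")
  }
  out <- data.frame(gene = results$gene, p = results$p,
                    n_deletions = results$n_deletions,
                    retained = retained, q = q, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "count_threshold") <- count_threshold
  out
}
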