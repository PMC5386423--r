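test_that("cumulative hazard integrates the step function", {
  flat <- incidence_model(0, 50, 0.01, "breast")
  expect_equal(cumulative_hazard(flat, 30), 0.3)
  expect_equal(cumulative_hazard(flat, 0), 0)
  # beyond the last band the final hazard extends
  expect_equal(cumulative_hazard(flat, 60), 0.6)

  two <- incidence_model(c(0, 25), c(25, 60), c(0.004, 0.02), "ovarian")
  for (t in c(0, 10, 25, 31.7, 60, 80)) {
    gridt <- seq(0, t, length.out = 200001)[-1]
    hz <- ifelse(gridt <= 25, 0.004, ifelse(gridt <= 60, 0.02, 0.02))
    riemann <- sum(hz) * (t / 200000)
    expect_lt(abs(cumulative_hazard(two, t) - riemann), 1e-5)
  }
  # piecewise closed form as the exact oracle
  expect_equal(cumulative_hazard(two, 31.7), 25 * 0.004 + 6.7 * 0.02,
               tolerance = 1e-10)
})

test_that("outcome classification follows the censoring rules", {
  ph <- rbind(pheno_row("A", bc = 38, oc = 45, last = 60),
              pheno_row("B", last = 60),
              pheno_row("C", mast = 40, bc = 42, last = 60))
  ph$age_bc_dx[3] <- 42 # events recorded even if after mastectomy
  bo <- build_outcomes(ph, "breast")
  expect_equal(bo$t, c(38, 60, 40))
  expect_equal(bo$delta, c(1L, 0L, 0L))
  oo <- build_outcomes(ph, "ovarian")
  expect_equal(oo$t[1], 38) # breast case unaffected at bc age
  expect_equal(oo$delta[1], 0L)
  expect_equal(oo$t[2], 60)

  # exhaustive case table: every combination of present/absent event ages
  ages <- list(bc = c(NA, 35), oc = c(NA, 42), mast = c(NA, 39),
               ooph = c(NA, 46))
  combos <- expand.grid(bc = ages$bc, oc = ages$oc, mast = ages$mast,
                        ooph = ages$ooph)
  ph_all <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    pheno_row(paste0("X", i), bc = combos$bc[i], oc = combos$oc[i],
              mast = combos$mast[i], ooph = combos$ooph[i], last = 55)))
  got_b <- build_outcomes(ph_all, "breast")
  got_o <- build_outcomes(ph_all, "ovarian")
  for (i in seq_len(nrow(combos))) {
    tb <- min(c(combos$bc[i], combos$oc[i], combos$mast[i], 55),
              na.rm = TRUE)
    expect_equal(got_b$t[i], tb)
    expect_equal(got_b$delta[i],
                 as.integer(!is.na(combos$bc[i]) && combos$bc[i] == tb))
    to <- min(c(combos$oc[i], combos$ooph[i], combos$bc[i], 55),
              na.rm = TRUE)
    expect_equal(got_o$t[i], to)
    expect_equal(got_o$delta[i],
                 as.integer(!is.na(combos$oc[i]) && combos$oc[i] == to))
  }
})

test_that("score test degenerates gracefully", {
  model <- default_incidence("breast")
  oc <- data.frame(sample = paste0("S", 1:6), t = c(35, 40, 45, 50, 55, 60),
                   delta = c(1, 0, 1, 0, 0, 0), endpoint = "breast")
  allz <- score_test(oc, rep(1, 6), model)
  expect_equal(allz$U, 0)
  expect_equal(allz$p, 1)
  expect_true(allz$degenerate)

  zero_model <- incidence_model(0, 100, 0, "breast")
  oc0 <- data.frame(sample = paste0("S", 1:4), t = c(30, 40, 50, 60),
                    delta = 0, endpoint = "breast")
  res0 <- score_test(oc0, c(1, 0, 1, 0), zero_model)
  expect_equal(res0$U, 0)
})

test_that("score statistic is the likelihood derivative at the null", {
  fx <- assoc_fixture()
  model <- default_incidence("breast")
  oc <- data.frame(sample = sprintf("S%02d", 1:20), t = fx$t,
                   delta = fx$delta, endpoint = "breast")
  res <- score_test(oc, fx$z, model)

  h <- 1e-5
  fd <- (retrospective_loglik(h, fx$z, fx$t, fx$delta, model) -
           retrospective_loglik(-h, fx$z, fx$t, fx$delta, model)) / (2 * h)
  expect_lt(abs(res$U - fd) / abs(fd), 1e-6)

  # chi-square close to the likelihood-ratio statistic
  opt <- optimize(function(b)
    retrospective_loglik(b, fx$z, fx$t, fx$delta, model),
    interval = c(-4, 4), maximum = TRUE, tol = 1e-9)
  lrt <- 2 * (opt$objective -
                retrospective_loglik(0, fx$z, fx$t, fx$delta, model))
  expect_lt(abs(res$chisq - lrt) / lrt, 0.15)

  # one-step estimate near the numerical MLE
  expect_lt(abs(res$beta_hat - opt$maximum), 0.35)
})

test_that("carrier enrichment among the affected raises U and the RR", {
  model <- default_incidence("breast")
  t <- rep(c(35, 55), each = 20)
  delta <- rep(c(1, 0), each = 20)
  oc <- data.frame(sample = sprintf("S%02d", 1:40), t = t, delta = delta,
                   endpoint = "breast")
  z_enriched <- c(rep(1, 8), rep(0, 12), rep(1, 2), rep(0, 18))
  z_depleted <- c(rep(1, 2), rep(0, 18), rep(1, 8), rep(0, 12))
  r1 <- score_test(oc, z_enriched, model)
  r2 <- score_test(oc, z_depleted, model)
  expect_gt(r1$U, 0)
  expect_gt(r1$rr, 1)
  expect_lt(r2$U, 0)
  expect_lt(r2$rr, 1)
  expect_true(r1$ci_lo < r1$rr && r1$rr < r1$ci_hi)
})

test_that("genome-wide scan skips empty genes and is permutation-stable", {
  model <- default_incidence("breast")
  set.seed(40)
  n <- 60
  samples <- sprintf("S%02d", 1:n)
  z <- cbind(G1 = rbinom(n, 1, 0.2), G2 = 0L, G3 = rbinom(n, 1, 0.3))
  rownames(z) <- samples
  cm <- structure(list(z = z, deletion_count = colSums(z),
                       genes = data.frame(symbol = colnames(z)),
                       samples = samples), class = "CarrierMatrix")
  oc <- data.frame(sample = samples, t = runif(n, 30, 65),
                   delta = rbinom(n, 1, 0.4), endpoint = "breast")
  gw <- run_genomewide(cm, oc, model)
  expect_equal(nrow(gw$results), 2)
  expect_equal(gw$skipped$gene, "G2")
  expect_equal(gw$skipped$reason, "no carriers")

  # permuting sample order leaves per-gene results unchanged
  perm <- sample(n)
  cm2 <- cm
  cm2$z <- cm$z[perm, ]
  cm2$samples <- samples[perm]
  gw2 <- run_genomewide(cm2, oc, model)
  expect_equal(gw2$results$chisq, gw$results$chisq)

  cm3 <- cm
  cm3$samples <- c(samples[-1], "GHOST")
  rownames(cm3$z)[n] <- "GHOST"
  expect_error(run_genomewide(cm3, oc, model), "GHOST")
})

test_that("effect recovery is self-consistent under ascertainment", {
  # one big cohort pins down the generator's attenuated expectation;
  # replicate estimates must agree with it, with the correct sign
  inc <- list(breast = default_incidence("breast"),
              ovarian = default_incidence("ovarian"))
  model <- inc$breast
  run_once <- function(n_per_stratum, seed) {
    set.seed(seed)
    pool <- matrix(rbinom(20 * n_per_stratum, 1, 0.05), ncol = 1,
                   dimnames = list(NULL, "L"))
    sim <- simulate_phenotypes(pool, "L", beta = log(2), incidence = inc,
                               n_target_per_stratum = n_per_stratum,
                               seed = seed + 1)
    z <- pool[sim$phenotypes$pool_row, "L"]
    oc <- build_outcomes(sim$phenotypes, "breast")
    score_test(oc, z, model)$beta_hat
  }
  big <- run_once(10000, 5000)
  reps <- vapply(1:50, function(r) run_once(1000, 6000 + 7 * r), numeric(1))
  expect_gte(sum(sign(reps) == sign(log(2))), 48)
  expect_lt(abs(mean(reps) - big), 3 * sd(reps) / sqrt(50))
  # attenuation: the retrospective one-step estimate under this design
  # stays below the generating log RR but well above zero
  expect_gt(mean(reps), 0.2)
  expect_lt(mean(reps), log(2) * 1.1)
})

test_that("discrete FDR filters sparse genes and matches BH by hand", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    p = c(0.01, 0.04, 0.5, 0.002),
                    n_deletions = c(10L, 7L, 4L, 3L))
  q <- discrete_fdr(res, count_threshold = 4)
  expect_true(is.na(q$q[q$gene == "D"]))
  expect_false(q$retained[q$gene == "D"])
  # BH on the retained three: p*(m/rank) with step-up monotonicity
  expect_equal(q$q[q$gene == "A"], 0.01 * 3 / 1)
  expect_equal(q$q[q$gene == "B"], 0.04 * 3 / 2)
  expect_equal(q$q[q$gene == "C"], 0.5)

  two <- data.frame(gene = c("A", "B"), p = c(0.01, 0.04),
                    n_deletions = 5L)
  expect_equal(discrete_fdr(two)$q, c(0.02, 0.04))

  ones <- data.frame(gene = c("A", "B"), p = 1, n_deletions = 5L)
  expect_equal(discrete_fdr(ones)$q, c(1, 1))

  none <- data.frame(gene = "A", p = 0.5, n_deletions = 1L)
  expect_warning(qn <- discrete_fdr(none), "no genes retained")
  expect_true(all(is.na(qn$q)))

  # q nondecreasing in p on the retained set
  set.seed(41)
  rnd <- data.frame(gene = paste0("G", 1:30), p = runif(30),
                    n_deletions = sample(2:10, 30, TRUE))
  qr <- discrete_fdr(rnd)
  keep <- qr[qr$retained, ]
  keep <- keep[order(keep$p), ]
  expect_true(all(diff(keep$q) >= -1e-12))
})
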