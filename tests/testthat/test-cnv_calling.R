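test_that("HMM caller is silent on clean diploid data", {
  rep <- flat_report(n = 200, baf = rep(c(0, 0.5, 1), length.out = 200))
  expect_equal(nrow(call_hmm(rep, "S1")), 0)
})

test_that("HMM recovers a noiseless deletion with exact boundaries", {
  n <- 200
  rep <- flat_report(n = n, baf = rep(c(0, 0.5, 1), length.out = n))
  del <- 96:105
  rep$lrr[del, 1] <- -0.66
  rep$baf[del, 1] <- rep(c(0, 1), 5)
  calls <- call_hmm(rep, "S1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, 1L)
  expect_equal(calls$start, rep$probes$position[96])
  expect_equal(calls$end, rep$probes$position[105])
  expect_equal(calls$n_probes, 10L)
  expect_gt(calls$confidence, 0)
  # call boundaries coincide with probe positions
  expect_true(all(c(calls$start, calls$end) %in% rep$probes$position))
})

test_that("Viterbi path equals the exhaustive-enumeration oracle", {
  cfg <- default_pipeline_config()
  hp <- cfg$hmm
  set.seed(20)
  for (case in 1:24) {
    n <- sample(5:8, 1)
    pos <- cumsum(sample(1000:20000, n))
    shift <- sample(c(0, -0.66, 0.4, -3.5), 1)
    k <- sample.int(n, 1)
    lrr <- rnorm(n, 0, 0.25)
    lrr[seq_len(k)] <- lrr[seq_len(k)] + shift
    baf <- runif(n)
    got <- cnvmod:::viterbi_cnv(lrr, baf, pos, hp$lrr_means,
                                rep_len(hp$lrr_sd, 5), hp$baf_sd,
                                hp$p_event, hp$dist_scale_bp)$states
    want <- oracle_best_path(lrr, baf, pos, hp)
    expect_equal(got, want, info = paste("case", case))
  }
})

test_that("segmentation caller finds step changes and ignores flat data", {
  rep <- flat_report(n = 200)
  expect_equal(nrow(call_segmentation(rep, "S1")), 0)

  set.seed(21)
  n <- 200
  del <- 101:120
  rep2 <- flat_report(n = n)
  rep2$lrr[, 1] <- rnorm(n, 0, 0.15)
  rep2$lrr[del, 1] <- rep2$lrr[del, 1] - 0.66
  calls <- call_segmentation(rep2, "S1")
  dels <- calls[calls$state == 1L, ]
  expect_equal(nrow(dels), 1)
  i1 <- match(dels$start, rep2$probes$position)
  i2 <- match(dels$end, rep2$probes$position)
  expect_lte(abs(i1 - 101), 1)
  expect_lte(abs(i2 - 120), 1)
})

test_that("noiseless step splits exactly at the changepoint", {
  x <- c(rep(0, 40), rep(-0.66, 30))
  ts <- cnvmod:::.split_tstats(x, 3)
  best_k <- ts$k[which.max(abs(ts$t))]
  # exhaustive oracle: |t| recomputed naively for every split
  tor <- vapply(ts$k, function(k) {
    a <- x[1:k]; b <- x[(k + 1):length(x)]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(x) - 2))
    se <- sp * sqrt(1 / length(a) + 1 / length(b))
    if (se == 0) ifelse(mean(a) == mean(b), 0, Inf) else
      (mean(a) - mean(b)) / se
  }, numeric(1))
  expect_equal(best_k, 40)
  expect_equal(ts$k[which.max(abs(tor))], 40)
})

test_that("consensus merging groups overlapping same-direction calls", {
  calls <- data.frame(
    sample = "S1", chromosome = "chr1",
    start = c(100L, 150L), end = c(200L, 260L),
    state = c(1L, 1L), n_probes = 5L, confidence = 10,
    caller = c("hmm", "seg"), stringsAsFactors = FALSE)
  cons <- merge_consensus(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, 2L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 260L)
  expect_equal(cons$direction, "deletion")

  # overlapping deletion and duplication stay separate
  mixed <- calls
  mixed$state <- c(1L, 3L)
  cons2 <- merge_consensus(mixed)
  expect_equal(nrow(cons2), 2)
  expect_setequal(cons2$direction, c("deletion", "duplication"))
})

test_that("consensus grouping equals connected components of overlaps", {
  set.seed(22)
  for (case in 1:10) {
    m <- sample(3:12, 1)
    st <- sample.int(5000, m)
    en <- st + sample.int(800, m)
    calls <- data.frame(sample = "S1", chromosome = "chr1",
                        start = st, end = en, state = 1L, n_probes = 3L,
                        confidence = 1,
                        caller = sample(c("hmm", "seg"), m, TRUE),
                        stringsAsFactors = FALSE)
    cons <- merge_consensus(calls)
    want_groups <- oracle_overlap_groups(st, en)
    expect_equal(nrow(cons), length(unique(want_groups)))
    # kept consensus calls for one sample/direction never overlap
    if (nrow(cons) > 1) {
      cons <- cons[order(cons$start), ]
      expect_true(all(cons$start[-1] > cons$end[-nrow(cons)]))
    }
    # every member interval lies inside its group union
    expect_equal(sum(cons$n_members), m)
  }
})

test_that("consensus filters apply length, support and MHC rules", {
  cons <- data.frame(
    sample = c("S1", "S1", "S2", "S2", "S2"),
    chromosome = c("chr1", "chr1", "chr6", "chr6", "chr2"),
    start = c(1000L, 5000L, 30000000L, 30050000L, 100L),
    end = c(1000999L, 6000L, 30010000L, 30060000L, 400L),
    direction = c("deletion", "deletion", "deletion", "duplication",
                  "deletion"),
    support = c(2L, 1L, 2L, 2L, 2L),
    callers = "hmm,seg", n_members = 2L, stringsAsFactors = FALSE)
  flt <- apply_consensus_filters(cons)
  # length exactly 1,000,000 bp -> removed (rule is >=)
  expect_true("length>=max_length_bp" %in% flt$removed$reason)
  expect_equal(flt$removed$start[flt$removed$reason == "length>=max_length_bp"],
               1000L)
  # support 1 -> removed
  expect_true(any(flt$removed$reason == "support<min_support"))
  # same-sample MHC deletion + duplication, both supported -> both removed
  mhc <- flt$removed[flt$removed$reason == "mhc_del_dup_conflict", ]
  expect_equal(nrow(mhc), 2)
  expect_setequal(mhc$direction, c("deletion", "duplication"))
  # the ordinary chr2 call survives
  expect_equal(flt$kept$chromosome, "chr2")
})

test_that("noise-free end-to-end calling recovers the truth set exactly", {
  quiet <- signal_model(lrr_sd = 0, baf_sd = 0, waviness_amplitude = 0)
  truth <- make_truth_set(probes_per_chromosome = 400, n_per_stratum = 20,
                          model = quiet, seed = 77)
  res <- run_cnv_pipeline(truth)
  got <- res$kept_calls[order(res$kept_calls$sample,
                              res$kept_calls$start), ]
  want <- truth$segments[order(truth$segments$sample,
                               truth$segments$start), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$sample, want$sample)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_true(all(got$direction == "deletion"))
})
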