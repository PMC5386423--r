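#' Signal model for synthetic SNP-array intensities
#'
#' Describes the generative model for probe signals: per-copy-number LRR
#' means (diploid at 0, hemizygous deletion negative), Gaussian LRR noise, a
#' sinusoidal low-frequency LRR wave standing in for GC-wave artifacts,
#' Gaussian scatter around the BAF genotype clusters, and an optional BAF
#' drift rate displacing homozygous BAF values into the drifted-homozygote
#' band.
#'
#' @param lrr_means length-5 numeric, LRR means for copy numbers 0..4.
#' @param lrr_sd Gaussian LRR noise s.d. (log2-ratio units).
#' @param baf_sd Gaussian BAF cluster s.d.
#' @param waviness_amplitude,waviness_wavelength_bp sinusoidal wave
#'   amplitude (LRR units) and wavelength (bp).
#' @param baf_drift_rate per-probe probability that a homozygous BAF value
#'   is displaced into the drift band.
#' @return list of class `SignalModel`.
#' @export
signal_model <- function(lrr_means = c(-3.5, -0.66, 0, 0.40, 0.68),
                         lrr_sd = 0.15, baf_sd = 0.03,
                         waviness_amplitude = 0.02,
                         waviness_wavelength_bp = 2e6,
                         baf_drift_rate = 0) {
  stopifnot(length(lrr_means) == 5, lrr_sd >= 0, baf_sd >= 0,
            waviness_amplitude >= 0, waviness_wavelength_bp > 0,
            baf_drift_rate >= 0, baf_drift_rate <= 1)
  if (lrr_means[2] >= 0) stop("copy-number-1 LRR mean must be < 0")
  structure(list(lrr_means = lrr_means, lrr_sd = lrr_sd, baf_sd = baf_sd,
                 waviness_amplitude = waviness_amplitude,
                 waviness_wavelength_bp = waviness_wavelength_bp,
                 baf_drift_rate = baf_drift_rate),
            class = "SignalModel")
}

#' Generate a probe grid
#'
#' Per-chromosome strictly increasing probe positions with exponential
#' inter-probe gaps (rounded up to at least 1 bp), emulating the irregular
#' marker spacing of a genotyping array.
#'
#' @param n_chromosomes,probes_per_chromosome positive integers.
#' @param mean_spacing_bp mean inter-probe gap in bp.
#' @param seed integer RNG seed.
#' @return `data.frame` with `probe_id`, `chromosome`, `position`.
#' @export
make_probe_grid <- function(n_chromosomes, probes_per_chromosome,
                            mean_spacing_bp, seed) {
  stopifnot(n_chromosomes >= 1, probes_per_chromosome >= 1,
            mean_spacing_bp >= 1)
  set.seed(seed)
  out <- lapply(seq_len(n_chromosomes), function(ch) {
    gaps <- pmax(1, round(rexp(probes_per_chromosome,
                               rate = 1 / mean_spacing_bp)))
    data.frame(probe_id = sprintf("chr%d_p%05d", ch,
                                  seq_len(probes_per_chromosome)),
               chromosome = paste0("chr", ch),
               position = as.integer(cumsum(gaps)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate deletion carrier genotypes
#'
#' Independent Bernoulli carrier draws per locus per sample; carriers are
#' heterozygous (copy number 1) unless `homozygous = TRUE`.
#'
#' @param loci `data.frame` with `locus`, `chromosome`, `start`, `end`,
#'   `frequency` (carrier frequency in `[0, 1]`); loci must not overlap.
#' @param n_samples number of samples.
#' @param seed integer RNG seed.
#' @return binary matrix, samples in rows, loci in columns.
#' @export
simulate_cnv_genotypes <- function(loci, n_samples, seed) {
  stopifnot(all(c("locus", "chromosome", "start", "end",
                  "frequency") %in% names(loci)))
  if (any(loci$frequency < 0 | loci$frequency > 1))
    stop("frequencies must lie in [0, 1]")
  for (chr in unique(loci$chromosome)) {
    l <- loci[loci$chromosome == chr, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1 && any(l$start[-1] <= l$end[-nrow(l)]))
      stop("overlapping loci on ", chr)
  }
  set.seed(seed)
  z <- vapply(loci$frequency,
              function(f) rbinom(n_samples, 1L, f),
              integer(n_samples))
  z <- matrix(as.integer(z), nrow = n_samples)
  dimnames(z) <- list(sprintf("S%05d", seq_len(n_samples)), loci$locus)
  z
}

#' Simulate array intensities with embedded CNVs
#'
#' LRR is the per-copy-number mean plus a per-sample-phase sinusoidal wave
#' plus Gaussian noise.  BAF is drawn from the genotype clusters implied by
#' the copy number, with population B-allele frequencies uniform per probe:
#' copy 2 gives clusters \{0, 1/2, 1\}, copy 1 \{0, 1\} (no heterozygous
#' band), copy 3 \{0, 1/3, 2/3, 1\}, copy 0 uniform noise on `[0, 1]`.
#'
#' @param grid probe grid from [make_probe_grid()].
#' @param truth list with `segments` (`sample`, `chromosome`, `start`,
#'   `end`, `cn`) and sample names in `samples`, or a `TruthSet`.
#' @param model a [signal_model()].
#' @param seed integer RNG seed.
#' @return An [intensity_report()].
#' @export
simulate_intensities <- function(grid, truth, model = signal_model(), seed) {
  segments <- truth$segments
  samples <- truth$samples
  if (is.null(samples)) samples <- rownames(truth$carriers)
  if (nrow(segments) > 0 &&
      !all(segments$chromosome %in% grid$chromosome))
    stop("truth segment on a chromosome absent from the probe grid")
  set.seed(seed)
  n <- nrow(grid)
  popb <- runif(n)
  lrr <- matrix(NA_real_, n, length(samples),
                dimnames = list(NULL, samples))
  baf <- lrr
  for (s in samples) {
    cn <- rep(2L, n)
    seg <- segments[segments$sample == s, , drop = FALSE]
    if (nrow(seg) > 0) {
      for (k in seq_len(nrow(seg))) {
        idx <- grid$chromosome == seg$chromosome[k] &
          grid$position >= seg$start[k] & grid$position <= seg$end[k]
        cn[idx] <- as.integer(seg$cn[k])
      }
    }
    phase <- runif(1, 0, 2 * pi)
    wave <- model$waviness_amplitude *
      sin(2 * pi * grid$position / model$waviness_wavelength_bp + phase)
    lrr[, s] <- model$lrr_means[cn + 1L] + wave + rnorm(n, 0, model$lrr_sd)
    g <- rep(NA_real_, n)
    pos_cn <- cn > 0
    g[pos_cn] <- rbinom(sum(pos_cn), cn[pos_cn], popb[pos_cn]) / cn[pos_cn]
    b <- g + rnorm(n, 0, model$baf_sd)
    b[!pos_cn] <- runif(sum(!pos_cn))
    if (model$baf_drift_rate > 0) {
      hom <- pos_cn & (g == 0 | g == 1)
      drift <- hom & runif(n) < model$baf_drift_rate
      lo <- drift & g == 0
      hi <- drift & g == 1
      b[lo] <- runif(sum(lo), 0.20, 0.25)
      b[hi] <- runif(sum(hi), 0.75, 0.80)
    }
    baf[, s] <- pmin(1, pmax(0, b))
  }
  intensity_report(grid, lrr, baf)
}

.invert_cumhaz <- function(model, H) {
  width <- model$age_end - model$age_start
  cum <- cumsum(model$hazard * width)
  K <- length(cum)
  k <- rowSums(outer(H, cum, ">")) + 1L
  t <- rep(Inf, length(H))
  inb <- k <= K
  if (any(inb)) {
    prev <- c(0, cum)[k[inb]]
    t[inb] <- model$age_start[k[inb]] +
      (H[inb] - prev) / model$hazard[k[inb]]
  }
  beyond <- !inb
  if (any(beyond) && model$hazard[K] > 0)
    t[beyond] <- model$age_end[K] + (H[beyond] - cum[K]) / model$hazard[K]
  t
}

.sample_onset <- function(model, rr) {
  H <- -log(runif(length(rr))) / rr
  .invert_cumhaz(model, H)
}

#' Simulate ascertained carrier phenotypes
#'
#' Draws age at onset by inverting the piecewise-exponential survival
#' function under hazard `lambda0(t) * exp(beta * z)` for the chosen
#' endpoint (the competing cancer keeps its baseline hazard), draws an
#' independent uniform censoring age, and rejection-samples candidates
#' until both ascertainment strata reach their targets: stratum A, breast
#' cancer diagnosed before age 40 (as first cancer); stratum B, no breast
#' cancer, or a first ovarian cancer at age 35 or older.
#'
#' @param carriers binary carrier matrix (candidate pool x loci).
#' @param locus name of the causal locus column.
#' @param beta log relative risk for carriers at that locus.
#' @param incidence list with `breast` and `ovarian` [incidence_model()]s.
#' @param censoring length-2 numeric, uniform censoring-age interval.
#' @param n_target_per_stratum samples required in each stratum.
#' @param seed integer RNG seed.
#' @param endpoint endpoint `beta` acts on.
#' @param max_attempts bound on candidate draws, as a multiple of the total
#'   target; exceeded before both strata fill raises an error.
#' @return list with `phenotypes` (validated phenotype `data.frame` plus
#'   `stratum` and `pool_row`), and `acceptance_rate`.
#' @export
simulate_phenotypes <- function(carriers, locus, beta, incidence,
                                censoring = c(25, 70),
                                n_target_per_stratum, seed,
                                endpoint = c("breast", "ovarian"),
                                max_attempts = 200) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.finite(beta), locus %in% colnames(carriers))
  set.seed(seed)
  need_a <- n_target_per_stratum
  need_b <- n_target_per_stratum
  acc <- list()
  drawn <- 0
  budget <- max_attempts * 2 * n_target_per_stratum
  while ((need_a > 0 || need_b > 0) && drawn < budget) {
    m <- min(budget - drawn, max(1000, 5 * (need_a + need_b)))
    rows <- sample.int(nrow(carriers), m, replace = TRUE)
    z <- carriers[rows, locus]
    rr_bc <- if (endpoint == "breast") exp(beta * z) else rep(1, m)
    rr_oc <- if (endpoint == "ovarian") exp(beta * z) else rep(1, m)
    t_bc <- .sample_onset(incidence$breast, rr_bc)
    t_oc <- .sample_onset(incidence$ovarian, rr_oc)
    cage <- runif(m, censoring[1], censoring[2])
    bc <- ifelse(t_bc <= cage, t_bc, NA)
    oc <- ifelse(t_oc <= cage, t_oc, NA)
    in_a <- !is.na(bc) & bc < 40 & (is.na(oc) | bc <= oc)
    in_b <- !in_a & (is.na(bc) | (!is.na(oc) & oc >= 35 & oc <= bc))
    take_a <- which(in_a)[seq_len(min(need_a, sum(in_a)))]
    take_b <- which(in_b)[seq_len(min(need_b, sum(in_b)))]
    take <- c(take_a, take_b)
    if (length(take) > 0)
      acc[[length(acc) + 1]] <- data.frame(
        pool_row = rows[take],
        age_bc_dx = bc[take], age_oc_dx = oc[take],
        age_last_obs = cage[take],
        stratum = rep(c("A", "B"), c(length(take_a), length(take_b))),
        stringsAsFactors = FALSE)
    need_a <- need_a - length(take_a)
    need_b <- need_b - length(take_b)
    drawn <- drawn + m
  }
  if (need_a > 0 || need_b > 0)
    stop("ascertainment stratum unfillable after ", drawn, " draws (",
         if (need_a > 0) "A" else "B", " short by ", max(need_a, need_b), ")")
  ph <- do.call(rbind, acc)
  ph <- ph[order(ph$stratum, ph$pool_row), ]
  out <- data.frame(sample = sprintf("S%05d", seq_len(nrow(ph))),
                    age_bc_dx = ph$age_bc_dx, age_oc_dx = ph$age_oc_dx,
                    age_mastectomy = NA_real_, age_oophorectomy = NA_real_,
                    age_last_obs = ph$age_last_obs, stratum = ph$stratum,
                    pool_row = ph$pool_row, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(phenotypes = out,
       acceptance_rate = nrow(out) / drawn)
}

.default_truth_loci <- function(grid, n_probes_per_locus = 15,
                                frequencies = c(0.010, 0.020, 0.034,
                                                0.050, 0.080)) {
  chroms <- unique(grid$chromosome)
  n_loci <- length(frequencies)
  chr_of <- chroms[((seq_len(n_loci) - 1) %% length(chroms)) + 1]
  out <- vector("list", n_loci)
  for (ch in chroms) {
    on_ch <- which(chr_of == ch)
    pos <- grid$position[grid$chromosome == ch]
    k <- length(on_ch)
    starts <- floor(length(pos) * seq_len(k) / (k + 1))
    for (j in seq_along(on_ch)) {
      i1 <- starts[j]
      i2 <- i1 + n_probes_per_locus - 1
      out[[on_ch[j]]] <- data.frame(
        locus = sprintf("L%d", on_ch[j]), chromosome = ch,
        start = pos[i1], end = pos[i2],
        frequency = frequencies[on_ch[j]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build a complete synthetic truth set
#'
#' Composes the probe grid, deletion loci, carrier genotypes, ascertained
#' phenotypes, and per-sample truth segments into one deterministic bundle.
#' Defaults define the study conditions used throughout the test suite:
#' five deletion loci with carrier frequencies spanning 1–8%, heterozygous
#' carriers, a causal locus with log relative risk `beta` acting on the
#' chosen endpoint, and two ascertainment strata of equal size.
#'
#' @param n_chromosomes,probes_per_chromosome,mean_spacing_bp probe grid
#'   parameters (see [make_probe_grid()]).
#' @param n_per_stratum ascertained samples per stratum.
#' @param loci optional loci `data.frame`; default places five loci with
#'   frequencies `c(0.010, 0.020, 0.034, 0.050, 0.080)`.
#' @param causal_locus name of the locus carrying the effect.
#' @param beta true log relative risk at the causal locus.
#' @param endpoint endpoint the effect acts on.
#' @param model [signal_model()] for the intensity simulation.
#' @param homozygous if `TRUE`, carriers get copy number 0 instead of 1.
#' @param pool_factor candidate-pool size as a multiple of the total
#'   target.
#' @param seed master integer seed; sub-seeds are derived from it.
#' @return list of class `TruthSet`: `grid`, `loci`, `carriers`,
#'   `segments`, `samples`, `phenotypes`, `acceptance_rate`, `params`.
#' @export
make_truth_set <- function(n_chromosomes = 2, probes_per_chromosome = 2000,
                           mean_spacing_bp = 5000, n_per_stratum = 100,
                           loci = NULL, causal_locus = "L5", beta = log(2),
                           endpoint = "breast", model = signal_model(),
                           homozygous = FALSE, pool_factor = 40, seed = 1) {
  grid <- make_probe_grid(n_chromosomes, probes_per_chromosome,
                          mean_spacing_bp, seed)
  if (is.null(loci)) loci <- .default_truth_loci(grid)
  pool_n <- pool_factor * 2 * n_per_stratum
  pool <- simulate_cnv_genotypes(loci, pool_n, seed + 1L)
  inc <- list(breast = default_incidence("breast"),
              ovarian = default_incidence("ovarian"))
  sim <- simulate_phenotypes(pool, causal_locus, beta, inc,
                             n_target_per_stratum = n_per_stratum,
                             seed = seed + 2L, endpoint = endpoint)
  phen <- sim$phenotypes
  carriers <- pool[phen$pool_row, , drop = FALSE]
  rownames(carriers) <- phen$sample
  cn_carrier <- if (homozygous) 0L else 1L
  segs <- list()
  for (j in seq_len(ncol(carriers))) {
    who <- rownames(carriers)[carriers[, j] == 1]
    if (length(who) > 0)
      segs[[length(segs) + 1]] <- data.frame(
        sample = who, chromosome = loci$chromosome[j],
        start = loci$start[j], end = loci$end[j], cn = cn_carrier,
        stringsAsFactors = FALSE)
  }
  segments <- if (length(segs) > 0) do.call(rbind, segs) else
    data.frame(sample = character(), chromosome = character(),
               start = integer(), end = integer(), cn = integer())
  rownames(segments) <- NULL
  structure(list(grid = grid, loci = loci, carriers = carriers,
                 segments = segments, samples = rownames(carriers),
                 phenotypes = phen[setdiff(names(phen), "pool_row")],
                 acceptance_rate = sim$acceptance_rate,
                 params = list(seed = seed, beta = beta,
                               causal_locus = causal_locus,
                               endpoint = endpoint, model = model,
                               n_per_stratum = n_per_stratum)),
            class = "TruthSet")
}

#' Write a truth set to tab-delimited files
#'
#' Emits `truth_loci.tsv`, `truth_carriers.tsv`, `truth_segments.tsv` and
#' `phenotypes.tsv` under `dir`; output is byte-identical across runs with
#' the same seed.
#'
#' @param truth a `TruthSet`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$loci, file.path(dir, "truth_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  carr <- data.frame(sample = rownames(truth$carriers), truth$carriers,
                     check.names = FALSE)
  write.table(carr, file.path(dir, "truth_carriers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$segments, file.path(dir, "truth_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_phenotype_table(truth$phenotypes, file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}
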