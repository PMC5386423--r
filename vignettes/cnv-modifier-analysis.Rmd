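---
title: "Deletion modifiers of cancer risk in BRCA1 carrier cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion modifiers of cancer risk in BRCA1 carrier cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmod)
```

## Scope

`cnvmod` implements a genome-wide scan for copy-number deletions that
modify breast or ovarian cancer risk in cohorts of *BRCA1*
pathogenic-variant carriers.  Such cohorts are not sampled at random:
they are typically assembled from one stratum of women diagnosed with
invasive breast cancer before age 40 and one stratum of women unaffected
by breast cancer (or with a first ovarian cancer at 35 or older).  The
pipeline therefore combines four ingredients:

1. consensus deletion calling from SNP-array Log R Ratio (LRR) and
   B-allele frequency (BAF) signals, with per-sample quality control;
2. delineation of deletion loci by transcript-union gene intervals and a
   1 bp overlap rule, yielding a binary carrier matrix;
3. a retrospective-likelihood score test of carrier status against
   censored age-at-onset outcomes, which remains valid under
   outcome-dependent sampling;
4. discrete-statistic false-discovery-rate control and
   validation-concordance arithmetic.

Because genotype-level cohort data of this kind cannot be redistributed,
the package ships a synthetic-data generator with known truth; every
stage is exercised end-to-end on simulated cohorts.

## The signal model and the synthetic cohort

A probe grid mimics an array of irregularly spaced markers:
per-chromosome positions with exponential gaps (default mean 5 kb,
matching a ~600k genome-wide array).  For each sample, LRR at a probe of
copy number $c$ is

$$\mathrm{LRR} = \mu_c + A \sin(2\pi x/\lambda + \phi_s) + \varepsilon,$$

with $\mu_{0..4} = (-3.5, -0.66, 0, 0.40, 0.68)$ (the classic log2-ratio
expectations for this array class), a per-sample-phase sinusoidal wave
(default amplitude $A = 0.02$, wavelength $\lambda = 2$ Mb) standing in
for GC-wave artifacts, and Gaussian noise ($\sigma = 0.15$, a typical
passing-sample value).  BAF is drawn from the genotype clusters implied
by the copy number with uniform population B-allele frequencies per
probe: copy 2 gives clusters $\{0, 1/2, 1\}$, a hemizygous deletion
$\{0, 1\}$ (the heterozygous band disappears), copy 0 pure noise.
Cluster scatter defaults to $\sigma_\mathrm{BAF} = 0.03$; an optional
drift rate displaces homozygous values into the $[0.20, 0.25] \cup
[0.75, 0.80]$ band to exercise the QC drift metric.

Deletion loci are Bernoulli carrier draws per sample (heterozygous by
default; homozygous behind a flag).  The default cohort carries five
loci with carrier frequencies 1, 2, 3.4, 5 and 8%, spanning the
frequency range over which array-called deletions of this kind have been
experimentally validated; the commonest locus carries the risk effect,
reflecting that power at these sample sizes is only realistic for the
common end of the spectrum.

Phenotypes follow a proportional-hazards model
$\lambda(t) = \lambda_0(t)\,e^{\beta z}$ with piecewise-constant
(decade-wise) baseline hazards.  The shipped defaults give cumulative
risks of roughly 75% (breast) and 45% (ovarian) by age 70 — the upper
end of published penetrance estimates for carriers from case-enriched
families, which is also the population such ascertainment designs
actually sample.  Onset ages are drawn by inverting the
piecewise-exponential survival function; censoring is uniform on
[25, 70] years, a single distribution into which end of follow-up and
prophylactic surgery are deliberately folded (the likelihood treats all
censoring identically).  Candidates are rejection-sampled into the two
ascertainment strata until each reaches its target; the acceptance rate
is recorded.  The generator does **not** emulate family structure,
SNP-level genotypes or linkage disequilibrium, duplication phenotype
effects, or locus-specific assay artifacts — so passing tests demonstrate
the statistical machinery under the stated signal model, not robustness
to everything real arrays do.

## Per-sample quality control

Metrics are computed over autosomal probes.  The tools that produced the
published exclusion thresholds do not document closed-form definitions,
so the package fixes concrete, testable ones and does not claim internal
fidelity to those tools:

* `lrr_sd` — s.d. of LRR;
* `baf_sd` — s.d. of BAF inside the heterozygous band [0.25, 0.75];
* `baf_drift` — fraction of probes with BAF in
  $[0.20, 0.25] \cup [0.75, 0.80]$, the drifted-homozygote band;
* `waviness_factor` — s.d. of 1 Mb-window LRR medians, signed by the
  lag-1 autocorrelation of the window sequence; windows with fewer than
  10 markers are dropped (a near-empty tail window would otherwise
  dominate the spread);
* outlier rates — fraction of values beyond 3 robust s.d.
  ($1.4826 \times \mathrm{MAD}$) of the sample median, separately for
  LRR and mid-band BAF.

Exclusion applies the published inequalities exactly, including their
strict/inclusive distinctions: LRR s.d. > 0.28, BAF drift > 0.01,
|waviness| > 0.05, BAF outliers > 0.1, LRR outliers ≥ 0.1, BAF s.d.
≥ 0.2, LRR s.d. ≥ 0.4.  A sample at exactly 0.28 is kept; one at
exactly 0.1 LRR outliers is excluded.

## CNV calling and consensus

Two independent in-package callers stand in for the external tool suite;
the consensus layer is caller-count-agnostic.

**HMM caller.** Five states (copy 0–4) over the ordered probes of each
chromosome.  Emissions sum an LRR term (Normal around the state mean,
default s.d. 0.20 — wider than the generator's noise, as a caller should
be) and a BAF term (equal-weight mixture over the state's genotype
clusters, uniform for copy 0).  Transition stay probability is
$1 - p_\mathrm{event}(1 - e^{-d/D})$ with inter-probe distance $d$ and
scale $D = 100$ kb, $p_\mathrm{event} = 0.01$, off-diagonal mass split
evenly; the initial distribution puts $1 - p_\mathrm{event}$ on diploid.
Viterbi decoding is exact (checked against exhaustive path enumeration
on small instances); maximal non-diploid runs of ≥ 3 probes become
calls, with confidence the decoded run's log-likelihood advantage over
the all-diploid path.

**Segmentation caller.** Recursive binary segmentation of LRR: each
segment splits at the position maximizing the absolute pooled-variance
two-sample t statistic, accepted when $|t| > 5$ with both sides keeping
≥ 3 probes.  A single chromosome-scale split cannot expose a short
interior event — a 15-probe deletion inside 2000 probes shifts the
full-length split statistic by only ~1.5 — so segments longer than
`max_seg_probes` (default 120) are always split at the maximizing
position and the threshold decision is made at that scale.  The forced
boundaries cost nothing: adjacent same-state segments are re-merged, so
splits inside homogeneous signal vanish, while a short event ends up at
a segment edge where its t statistic is undiluted (for an interior
event, $|t| \approx m\,\Delta/(\sigma\sqrt{L})$ in a segment of length
$L$, which crosses 5 near $L \approx 120$ for a 15-probe, $-0.66$
shift at $\sigma = 0.15$).  Final segments are classified by mean LRR
(< −2 copy 0, < −0.3 copy 1, > 0.25 copy 3).

**Consensus.** Per sample and direction, calls overlapping by ≥ 1 bp are
grouped transitively; each group becomes one call spanning the union
interval (union rather than intersection keeps the downstream 1 bp gene
overlap monotone in its inputs), supported by the distinct callers
contributing.  Filters then remove calls ≥ 1000 kb long (boundary
inclusive), calls supported by a single caller, and — within the
configured MHC interval (default chr6:29.6–33.1 Mb) — same-sample
deletion/duplication pairs that each retain the required support, which
are mutually contradictory artifacts.

## Gene overlap and carrier frequencies

Gene intervals span the start of the earliest to the end of the latest
alternate transcript of a symbol (a symbol on two chromosomes is an
error).  Sample–gene carrier status is a ≥ 1 bp overlap between a kept
consensus deletion and the gene interval, computed with an interval
index and verified against a quadratic brute force in the tests;
coordinates are 1-based inclusive internally and 0-based half-open in
BED output.  A sample with several deletions over one gene counts once
(dominant coding).  The reported per-locus frequency is the **carrier
proportion** carriers/N: published per-locus figures for this design
reproduce from carrier counts under that convention (79 carriers in
2319 samples prints as 3.4%), and the allele-count convention
carriers/2N is emitted alongside for reference.  Duplications are
excluded from the matrix: their genomic location is not determined by
the array signal, and deletion events dominate the validated
risk-associated loci.

## Retrospective-likelihood association

For the breast endpoint, each carrier is classified at first breast
cancer diagnosis, censored at ovarian cancer diagnosis or bilateral
prophylactic mastectomy — whichever occurred first — or at last
observation; ties classify as affected.  For the ovarian endpoint,
classification is at ovarian cancer diagnosis, censoring at
oophorectomy or last observation, with breast-cancer cases treated as
unaffected at their breast-cancer age.

Because sampling depends on phenotype, the likelihood is the probability
of the carrier genotype *given* the phenotype,
$P(z \mid \delta, t)$, under hazard $\lambda_0(t) e^{\beta z}$ and
carrier probability $p$:

$$P(\delta = 1, t \mid z) \propto \lambda_0(t) e^{\beta z}
  \exp\!\left(-\Lambda_0(t) e^{\beta z}\right), \qquad
  P(\delta = 0, t \mid z) = \exp\!\left(-\Lambda_0(t) e^{\beta z}\right).$$

With $\hat p = \bar z$ (the null MLE) and
$w_i = \delta_i - \Lambda_0(t_i)$, the score at $\beta = 0$ is
$U = \sum_i (z_i - \hat p)\, w_i$, which the tests verify numerically as
the derivative of the implemented log-likelihood.  Since $p$ is
estimated, the null variance of $U$ is that of the *efficient* score,

$$V = \hat p (1 - \hat p) \sum_i (w_i - \bar w)^2,$$

not $\hat p(1-\hat p)\sum w_i^2$: centering $w$ leaves $U$ unchanged
(the $z_i - \hat p$ sum to zero) but removes the variance inflation from
the nuisance estimate, which matters in ascertained cohorts where
$\bar w \ne 0$.  With the uncentered form the simulated null rejection
rate at nominal 0.05 sits near 0.042; with the efficient-score form it
is indistinguishable from 0.05.  $U^2/V$ is referred to $\chi^2_1$; the
approximate relative risk is the one-step estimate $e^{U/V}$ with 95% CI
$e^{U/V \pm 1.96/\sqrt V}$.  The one-step estimate is not the MLE and
attenuates for large effects; the tests cross-check $U^2/V$ against the
numerically maximized likelihood-ratio statistic (15% tolerance) and the
one-step estimate against the numerical MLE.

The baseline incidence used by the analysis ships as configuration (the
same decade-wise tables the generator uses), so the simulation studies
are self-consistent without external rate tables.  Beyond the last age
band the final hazard extends; $V = 0$ yields a degenerate result with
p = 1 and an undefined RR rather than an error.

Multiplicity uses a discreteness filter before Benjamini–Hochberg:
genes with fewer than 4 total deletions cannot produce informative
small p-values under their discrete null and are excluded from the
correction entirely (q-value missing, flagged), and BH step-up q-values
are computed on the retained set.  Filtering on the deletion *count* is
independent of the observed p-values, so the correction remains valid.

## Validation concordance

Detection metrics against a truth set count a truth segment as detected
if a same-sample kept deletion overlaps it by ≥ 1 bp, and a call as
confirmed if it overlaps same-sample truth.  Sensitivity is
detected/(detected + missed).  "Specificity" is deliberately implemented
as the fraction of calls confirmed — positive predictive value — because
true negatives are uncountable in this design; the terminology follows
how such studies report it.  Reported percentages round to the nearest
integer, halves away from zero.

## Numerical and design notes

* All generators are pure functions of (parameters, seed); master seeds
  derive sub-seeds by small offsets.
* The retrospective log-likelihood uses log-sum-exp for the per-sample
  denominator; the baseline-hazard log term is skipped for censored
  records (it multiplies $\delta$).
* Outcome ties (an event age equal to a censoring age) classify as
  affected; event ages after the recorded last observation are
  validation errors, not silently truncated.
* The test suite and acceptance script run the full pipeline on cohorts
  of 2 chromosomes × 2000 probes × 200 samples (plus a noise-free
  2 × 400 × 40 cohort for exact-recovery checks), 2000 null simulations
  of 500 samples for calibration, and 50 (suite) or 20 (script) seeded
  end-to-end replicates for causal-locus ranking — sizes chosen to keep
  a full run on a single CPU in minutes while leaving Monte-Carlo error
  well inside the asserted tolerances.

## Limitations

* Samples are treated as independent; real carrier cohorts contain
  relatives, and no kinship adjustment is implemented.
* At 200 ascertained samples and carrier frequencies ≤ 8%, the score
  test's noncentrality for a relative risk of 2 is modest (≈ 3–5); the
  causal locus ranks in the top 2 of 5 loci in roughly 80% of
  replicates, so single small cohorts should be read as
  hypothesis-generating — consistent with how association results at
  this scale are reported.
* The QC metric definitions are this package's own; fidelity to the
  internals of the external tools whose thresholds they host is not
  claimed.
* The consensus merge rule (union, ≥ 1 bp, transitive) is one defensible
  choice among several; the downstream gene-overlap test is monotone in
  it by construction.
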