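# cnvmod

Genome-wide analysis of copy-number **deletions** as modifiers of breast
and ovarian cancer risk in cohorts of *BRCA1* pathogenic-variant
carriers.

Carrier cohorts of this kind are ascertained through disease — typically
one stratum diagnosed with invasive breast cancer before age 40 and one
stratum unaffected (or with a first ovarian cancer at 35 or older) — so
ordinary prospective survival analysis is biased.  `cnvmod` implements
the full pipeline such a study needs, exercised end-to-end on synthetic
cohorts with known truth:

* **Consensus CNV calling** from SNP-array Log R Ratio / B-allele
  frequency signals: per-sample QC with the published exclusion
  thresholds, a five-state distance-aware hidden Markov model caller and
  an independent binary-segmentation caller, merged per sample by ≥ 1 bp
  transitive overlap with filters for events ≥ 1000 kb, single-caller
  support, and contradictory MHC-region calls.
* **Gene-region delineation**: transcript-union gene intervals, ≥ 1 bp
  overlap carrier matrices (deletions only), carrier-proportion
  frequencies.
* **Retrospective-likelihood score test**: with censored analysis age
  `t`, affected indicator `δ`, carrier indicator `z`, baseline
  cumulative hazard `Λ0`, and `p̂ = mean(z)`, the statistic is

      U = Σ (z_i − p̂) w_i,   w_i = δ_i − Λ0(t_i)
      V = p̂(1 − p̂) Σ (w_i − w̄)²          (efficient-score variance)
      U²/V ~ χ²₁,   RR ≈ exp(U/V),  95% CI exp(U/V ± 1.96/√V)

  valid under outcome-dependent sampling because it conditions on the
  observed phenotype.
* **Discrete FDR**: genes with fewer than 4 deletions are excluded from
  multiplicity correction; Benjamini–Hochberg q-values on the rest.
* **Validation concordance**: detection sensitivity/positive predictive
  value against a truth set, validation rates, false-negative rates,
  CNV-map overlap summaries.
* **Synthetic-data generator**: probe grids, intensity signals with
  embedded deletions, waviness and BAF drift, carrier genotypes, and
  two-stratum ascertained phenotypes from piecewise-exponential
  penetrance — all deterministic under a seed.

## Worked example

Simulate an ascertained cohort of 200 carriers (100 early-onset breast
cancer cases, 100 unaffected/ovarian) typed on a 2-chromosome ×
2000-probe grid, with five deletion loci (carrier frequencies 1–8%) of
which the commonest, `L5`, doubles breast cancer hazard; then run the
whole pipeline:

```r
library(cnvmod)
truth <- make_truth_set(seed = 1)          # known ground truth
pipe  <- run_cnv_pipeline(truth)           # QC -> calls -> consensus
                                           # -> overlap -> association
length(pipe$kept_samples)                  # 200 samples pass QC
nrow(pipe$kept_calls)                      # 43 consensus deletions kept
pipe$association[order(pipe$association$p),
                 c("gene", "carriers", "carrier_freq", "p", "rr",
                   "rr_ci", "n_deletions", "q")]
```

```
 gene carriers carrier_freq      p    rr            rr_ci n_deletions     q
   L5       18        0.090 0.0541 2.011 2.01 (0.99–4.09)          18 0.217
   L4       11        0.055 0.5166 1.344 1.34 (0.55–3.28)          11 0.860
   L3        7        0.035 0.6451 1.297 1.30 (0.43–3.93)           7 0.860
   L2        3        0.015 0.7976 0.803 0.80 (0.15–4.29)           3    NA
   L1        4        0.020 0.9639 1.034 1.03 (0.24–4.42)           4 0.964
```

The causal locus ranks first with an estimated relative risk of 2.0
(the generating value), its observed carrier frequency (9.0%) is
ascertainment-enriched above the generating 8%, and `L2` — with only 3
deletions — is excluded from q-value correction by the discrete-count
filter (`q = NA`).  All 43 kept consensus deletions coincide with truth
segments here; `write_calls_bed()` and `write_association_table()`
export the standard interchange files.

The methods vignette (`vignettes/cnv-modifier-analysis.Rmd`) documents
the signal model, the caller and consensus rules, the retrospective
likelihood and its efficient-score variance, and the generator's
limitations.

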