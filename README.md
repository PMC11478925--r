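# mrsdx

Noninvasive decision support for the three major childhood cerebellar
tumours — pilocytic astrocytoma (PA), ependymoma (EP) and medulloblastoma
(MB) — from short-echo single-voxel ¹H MR spectroscopy. The package is
aimed at researchers in clinical MRS and machine-learning diagnostics who
need a complete, testable re-implementation of the pipeline that takes a
raw free induction decay to a tumour-type call with a confidence measure,
plus the statistics used to quantify what such a tool adds to
conventional radiology reading.

## What it does

* **Simulation** — a 26-component spectral basis (16 metabolites, 9
  macromolecule/lipid resonances grouped as MMLip09/13/20, and a negative
  −CrCH₂ singlet at 3.94 ppm) drives a PRESS forward model (1.5 T, TE
  30 ms, TR 1500 ms, 1.024 Hz per point) with class-conditional
  concentration distributions, phase/eddy-current artifacts, noise, and an
  8-average water reference. Radiologist certainty tables for a staged
  reader study are simulated too.
* **Preprocessing** — Klose-style eddy-current correction from the water
  reference, Fourier transformation with a calibrated ppm axis, automatic
  zero-/first-order phasing (model-based when a basis is available), and
  water-peak normalization.
* **Quantification** — linear-combination fitting of the real spectrum
  over 0.2–4.0 ppm: non-negative basis amplitudes, a penalised cubic
  spline baseline with 0.15 ppm knots, a global frequency-shift and
  line-broadening search, water-referenced concentrations in mM (assumed
  water 35,880 mM), and Cramér–Rao lower bounds marginalised over every
  free parameter.
* **Quality control** — spectrum gates (SNR, linewidth, convergence) and
  the feature rule "CRLB < 30% in at least two subjects", yielding the
  19 analysis variables (16 metabolites + 3 MMLip groups).
* **Classification** — linear discriminant analysis on
  training-standardized features: for class *k*,
  `g_k(z) = zᵀΣ̂⁻¹m_k − ½ m_kᵀΣ̂⁻¹m_k + log π_k`, posteriors by softmax,
  canonical discriminant-function (DF) scores, decision boundaries and
  boundary distances; covariance shrinkage for small cohorts.
* **Decision support** — a three-panel report per case (standardized
  metabolite profile, DF scatter with boundaries and the index case,
  index spectrum over per-class mean spectra with 95% bands) plus a JSON
  sidecar.
* **Reader-study statistics** — diagnostic accuracy under the strict
  ">50% certainty" rule, certainty-when-correct summaries, per-case
  certainty changes with an exact-enumeration Wilcoxon signed-rank test
  and Hodges–Lehmann intervals, Brown–Forsythe Levene test,
  Kruskal–Wallis, and per-metabolite ANOVA with Bonferroni-adjusted
  pairwise t-tests.

## Worked example

```r
library(mrsdx)

# quantify one simulated subject
basis  <- build_default_basis()
params <- acq_params(n_points = 1024)
cohort <- sample_cohort(default_class_params(), c(PA = 4, EP = 3, MB = 4),
                        basis, params, seed = 42)
subj <- quantify_subject(cohort$fid[[1]], cohort$water_ref[[1]], basis)
head(subj$features, 5)
#> # A tibble: 5 × 3
#>   feature   value crlb_pct
#>   <chr>     <dbl>    <dbl>
#> 1 Ala     0.756       52.2
#> 2 Asp     0.00529    999
#> 3 Cr      3.12        11.1
#> 4 Glc     2.58        28.9
#> 5 Gln     2.24        22.5
```

`value` is the water-referenced concentration in mM; `crlb_pct` is the
relative Cramér–Rao bound (999 marks an undefined bound, here a
zero-amplitude component). This subject is a PA: creatine is low
(3.1 mM) and its CRLB of 11% would pass the 30% quality gate, while
aspartate is not quantifiable.

```r
# end-to-end: simulate, preprocess, fit, QC, train, classify prospectively
run <- run_pipeline(pipeline_config(n_train = c(PA = 8, EP = 5, MB = 8),
                                    n_test  = c(PA = 4, EP = 3, MB = 4),
                                    seed = 42, n_points = 1024))
run
#> <mrs_pipeline_run> seed 42, 21 train / 11 test after QC, accuracy 91%
run$evaluation$confusion
#>      predicted
#> truth EP MB PA
#>    EP  3  0  0
#>    MB  0  4  0
#>    PA  1  0  3

# staged reader study: does certainty in the correct diagnosis rise?
tbl <- sample_certainty_table(rep(c("PA", "EP", "MB"), 11), seed = 42)
d   <- certainty_change(tbl, "imaging", "imaging+MRS+DSS")
wilcoxon_signed_rank(d$delta[d$rater == "rad1"])
#> # A tibble: 1 × 7
#>   statistic     p_value method               n_used median conf_low conf_high
#>       <dbl>       <dbl> <chr>                 <int>  <dbl>    <dbl>     <dbl>
#> 1       559 0.000000679 normal approximation     33   18.0     14.2      21.3
```

The held-out confusion matrix shows one PA called EP (11 test cases,
10 correct, 91% after rounding); the signed-rank test says this
simulated rater's certainty in the correct diagnosis rose by a median of
18 percentage points (95% CI 14–21) across the three review stages.

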