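---
title: "Models and methods behind mrsdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrsdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsdx)
```

mrsdx implements a complete decision-support pipeline for diagnosing the
three major childhood cerebellar tumours — pilocytic astrocytoma (PA),
ependymoma (EP) and medulloblastoma (MB) — from short-echo single-voxel
proton MR spectroscopy: spectrum simulation, preprocessing,
linear-combination metabolite quantification with Cramér–Rao lower bounds
(CRLBs), quality control, a linear discriminant classifier with posterior
probabilities, a three-panel decision-support display, and the statistics
used to evaluate a staged radiology reader study. This vignette records
the models, the tunable parameters, and the design choices made where the
design was genuinely open.

## The forward model and the synthetic generator

Patient spectra of this kind are not publicly distributable, so every
stage is exercised against a synthetic cohort generator whose defaults
mirror a 1.5 T PRESS acquisition: TE 30 ms, TR 1500 ms, 2048 complex
points (1024 supported), a filter bandwidth of `1.024 * n_points` Hz so
the spectral resolution is 1.024 Hz per point, cubic voxels of 1.5–2 cm,
128 water-suppressed averages and an 8-average unsuppressed water
reference.

The basis set has 26 components: 16 metabolites (Ala, Asp, Cr, Glc, Gln,
Glu, Gly, GPC, Gua, Ins, Lac, NAA, NAAG, PCh, Scyllo, Tau), nine
macromolecule/lipid resonances grouped by proximity to 0.9, 1.3 and
2.0 ppm, and a negative creatine-methylene singlet at 3.94 ppm. The
published abbreviation list names 13 metabolites; we complete the count
to 16 with Asp, Gly and NAAG, which belong to any conventional short-echo
tumour basis. Multiplets are simplified to fixed peak lists (chemical
shift, amplitude proportional to proton count, linewidth, Lorentzian or
Gaussian shape) rather than density-matrix simulations; the fitting
mathematics is unaffected by this simplification, but real coupled
multiplet shapes (and their TE dependence) are one of the features of
real data that passing tests do not probe.

A free induction decay is the concentration-weighted sum of component
FIDs, times `exp(i(phi0 + phi_eddy(t)))` with an exponentially decaying
eddy-current phase, plus complex Gaussian noise; first-order phase error
is applied as a continuous frequency-domain ramp (a per-peak constant
phase would be unphysical and is not invertible by any linear-phase
correction). The water reference holds one resonance at 4.7 ppm with
amplitude equal to the assumed water concentration of 35,880 mM, so the
water-referenced concentration scale is self-consistent, and carries the
same eddy-current phase with noise scaled to its 8 averages.

Class-conditional concentration means encode the qualitative contrasts
that separate the tumour types at short echo time — MB: high total
choline, taurine present, low myo-inositol; EP: high myo-inositol and
creatine; PA: low creatine, prominent lactate and the highest
macromolecule/lipid levels (consistent with lipid-rich cases gravitating
toward PA in classification). No published concentration table is
reproduced; values are plausible mM magnitudes held as configuration,
with a default diagonal covariance at 25% coefficient of variation and
negative draws resampled (up to 100 attempts) rather than clipped, to
preserve the distribution shape. Artifact parameters are drawn uniformly:
zero-order phase ±30°, first-order ±4°/ppm, eddy amplitude 0–1 rad with a
20–80 ms decay, and a time-domain noise SD of 2–4 instrument units, which
yields spectrum SNRs in the clinically typical 5–25 range.

The simulated reader study assigns each case, rater and review stage a
certainty triple over {PA, EP, MB} summing to 100. The truth-class
certainty starts near 55 ± 15 and shifts at each later stage by the
rater's stage effect plus noise (SD 7), the other two certainties being
rescaled to preserve the sum. The default per-rater stage effects
(9 + 7, 3 + 5, 10 + 10 percentage points) emulate a regime in which the
median certainty of the correct diagnosis rises by roughly 8–20 points
from conventional imaging to the full decision-support stage, with
rater-to-rater variation in both size and spread.

## Preprocessing

Eddy-current correction is the classical point-wise phase subtraction:
sample k of the water-suppressed FID is multiplied by
`exp(-i arg(wref_k))`. Only the unit-magnitude phasor is used (no
magnitude deconvolution). Where the reference magnitude falls below a
relative threshold (default 1e-3 of its maximum) the phase of the last
usable sample is carried forward: deep in the decay the reference phase
is noise, and freezing it prevents the correction from injecting noise
into the tail.

Fourier transformation scales by the dwell time, so spectrum integrals in
Hz units equal time-domain amplitudes; the ppm axis is ascending
internally and reversed only at display time. Optional Hanning
apodization (700 ms width) and zero filling reproduce a scanner-style
display mode; the fitting pipeline applies neither.

Automatic zero-/first-order phasing was specified as negative-real-area
minimization with a grid-seeded Nelder–Mead search. Implementing it
showed the criterion is degenerate on sparse spectra: any phase roll that
vanishes at the peak positions also scores zero, so a whole valley of
(phi0, phi1) pairs — including badly wrong ones — minimises it. The
shipped `auto_phase()` therefore works in two stages: peak phases are
measured by symmetric complex integrals around sub-bin-interpolated peak
maxima (after subtracting a locally interpolated complex background that
carries the dispersive tails of distant peaks), the linear phase model is
fitted by weighted circular regression, and the negativity criterion only
polishes the result locally, with the identity kept whenever it scores no
worse. When a basis set is supplied, phasing is model-based instead: the
criterion is the residual of a non-negative linear-combination fit, which
pins both phase orders to well under a degree because dispersive
lineshapes cannot be mimicked by non-negative absorption shapes. The
quantification pipeline uses the model-based mode. The first-order pivot
is 3.0 ppm (centre of the metabolite region); reported phi1 values depend
on this choice.

Water normalization divides by the magnitude maximum of the reference
spectrum within 4.2–5.2 ppm — a peak-height rather than integral metric,
robust to residual phase — and requires the peak to exceed five times the
reference noise SD.

## Linear-combination fitting and CRLBs

The fitter minimises, over a 0.2–4.0 ppm window (standard short-TE
practice, excluding residual water), the squared distance between the
real part of the spectrum and a non-negative combination of basis
component spectra plus a penalised cubic B-spline baseline with knots
every 0.15 ppm (the conventional baseline knot spacing). A global
frequency shift (±0.05 ppm) and a global extra Lorentzian broadening
(0–5 Hz) are optimised by a bounded quasi-Newton outer search; inside
each outer evaluation the baseline is projected out analytically and the
amplitudes are solved by non-negative least squares. The specification
allowed per-component shifts and dampings; the shipped default is the
global pair, which keeps the nonlinear search two-dimensional and is
sufficient for rigid-shift data — per-component refinement is the natural
extension if field drift across the spectrum ever matters. The negative
creatine-methylene component keeps its fixed negative shape with a
non-negative multiplier, so it can only subtract.

The baseline roughness penalty (second differences of the spline
coefficients) is chosen by generalized cross-validation over a log-spaced
grid on the unconstrained ridge problem, then held fixed for the
constrained solve; if GCV is degenerate the weight falls back to 1. The
noise SD is estimated as `sd(diff(residual))/sqrt(2)` — a first-difference
estimator that ignores smooth lack-of-fit — because synthetic spectra
offer no guaranteed signal-free region inside the window.

CRLBs are `100 * sqrt([(J'J + P)^-1]_cc) * sigma / a_c`, marginalised
over all free parameters: the jacobian includes every basis column, every
spline coefficient and the two nonlinear parameters, and P carries the
baseline penalty so the bound describes the regularised estimator
actually used. The information matrix is equilibrated before inversion so
that a nearly collinear pair (GPC and PCh, whose trimethyl resonances sit
0.01 ppm apart) inflates only its own variances; exactly collinear
columns make the matrix singular, and any amplitude with weight in its
null space is flagged at 999%, the conventional "undefined" sentinel, as
are zero amplitudes. Broad macromolecule components overlap the spline
baseline almost completely — their individual CRLBs are honestly large,
which is why grouped variables are assessed on the minimum CRLB over
members.

Concentrations are `a_c / A_water * 35880 mM`, where the water amplitude
is the integral of the complex reference spectrum over the whole axis —
equal to the first time-domain sample, hence independent of the water
linewidth. Proton-count correction defaults to 1 because the synthetic
basis is amplitude-calibrated per mM; a per-component correction vector
is accepted for bases calibrated otherwise. T1/T2 relaxation and tissue
water fraction corrections are out of scope. Diagnostics: SNR is the
tallest median-centred data point over twice the noise SD (the median
stands in for the baseline level because an almost-unpenalised spline can
oscillate at the window edges); FWHM is measured on the tallest single
fitted resonance, not on a multiplet envelope, so it reflects line
broadening rather than composition.

## Quality control and feature selection

A feature enters the analysis if its CRLB is strictly below 30% in at
least two subjects; the 19 analysis variables are the 16 metabolites plus
MMLip09/13/20 group sums. Spectrum-level gates — SNR at least 4, FWHM at
most 0.1 ppm, and a converged fit — are conventional defaults, exposed as
configuration and not claimed as reproductions of any inherited
protocol-specific thresholds.

## The classifier

Features are standardized by the training mean and SD (test cases reuse
the training statistics; nothing is re-estimated at test time, and an
immutability test enforces this). The discriminant for class k is
`g_k(z) = z'S⁻¹m_k − m_k'S⁻¹m_k/2 + log pi_k` with pooled within-class
covariance S, optionally shrunk toward its diagonal with weight
lambda = 0.1 by default — at a training size near 34 cases with up to 19
variables the pooled covariance is otherwise close to singular; lambda = 0
restores classical LDA exactly. Priors default to uniform, with
training-frequency priors behind a flag. Posteriors are the softmax of
the discriminants, exact for the shared-covariance Gaussian model. Ties
break in lexicographic class order (EP < MB < PA). Accuracy is reported
as round-half-up percent alongside the exact fraction, so 30/33 prints
as 91%.

Canonical discriminant-function (DF) axes come from the two leading
eigenvectors of the within/between eigenproblem, scaled so the
within-class covariance of DF scores is the identity; with three classes
the class information lives entirely in this plane, so decision
boundaries are drawn there as the piecewise-linear loci where the top two
posteriors are equal, and the reported boundary distance is the
Mahalanobis-scaled gap between the two leading discriminants. The
original classifier's coefficients are not published, so the model is
retrained on the synthetic cohort and all validation is property-based:
posteriors against brute-force Gaussian densities, held-out accuracy
against a Monte-Carlo Bayes rate, boundary geometry against closed forms.

## The decision-support display

The report shows, for one index case: the standardized feature z-scores
as bars (exactly the values the classifier consumed — a single source of
truth, and the axis is labelled as z-scores since the published display's
normalisation is not stated); the DF-score scatter of the training cohort
with boundaries and the index case marked; and the index spectrum
overlaid on per-class mean spectra. Mean spectra are computed from
baseline-subtracted, water-normalized spectra (enforced by tag) with
pointwise t-based 95% confidence bands; a percentile-bootstrap band over
subjects is available via `ci_method = "bootstrap"`, but the t-interval
is the default because the published figures state only "95% confidence
intervals". Spectra are
displayed over 0.5–4.3 ppm with ppm decreasing rightward. A JSON sidecar
carries posteriors, DF scores, nearest class and boundary distance.

## Reader-study statistics

Two distinct correctness predicates are implemented, mirroring how such
studies report: *diagnostic accuracy* counts a case correct only when the
certainty on the true diagnosis strictly exceeds 50%, while *certainty
when correct* conditions on the truth class holding the strict maximum
certainty even if that maximum is 50 or less; ties count as incorrect.
Certainty changes are per-case differences of truth-class certainty
between stages, paired by case id.

The Wilcoxon signed-rank test drops zero differences by default (Pratt's
variant keeps them in the ranking behind a flag). For up to 15 effective
observations the null distribution is enumerated over all 2^n sign
assignments, which remains exact under tied ranks; beyond that a normal
approximation with tie and continuity corrections is used — both are
available because at n = 33 either could have been the published choice.
The accompanying location estimate is the Hodges–Lehmann pseudo-median
with a Walsh-average confidence interval. Levene's test defaults to the
median-centred Brown–Forsythe form (mean-centred behind a flag);
Kruskal–Wallis uses the tie-corrected H with a chi-square p-value and an
optional exact enumeration for ten or fewer observations; metabolite
comparisons are per-metabolite one-way ANOVA with Bonferroni-adjusted
pairwise Welch t-tests.

## Problem sizes and what the tests show

The shipped checks run the quantifier on 50 spectra at SNR near 10
(median absolute relative error of Cr, NAA and total choline within 10%,
and at least 90% coverage of truth by ±2 CRLB intervals), verify the
singlet CRLB against its closed form to 1e-6, invert known eddy-current
and phase distortions to below the acquisition noise floor, match LDA
posteriors to brute-force densities at 1e-9, reach a 2000-case
Monte-Carlo Bayes rate within 3 points, cross-check every statistic
against enumeration or closed forms, and confirm that a 100-replicate
reader-study simulation at n = 33 is significant at p < 0.001 in at
least 90% of replicates. The full pipeline demonstration trains on a
12/4/18 case mix and classifies a 16/3/14 prospective cohort — the
post-QC sizes of the study the package emulates.

What passing these tests does *not* show: performance on real coupled
multiplets, B0 inhomogeneity, residual water, frequency drift across
averages, vendor raw formats, or relaxation-corrected absolute
quantification — all explicitly out of scope.
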