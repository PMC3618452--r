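---
title: "Methods: simulation, bucketing, OPLS-DA and inference in nmropls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, bucketing, OPLS-DA and inference in nmropls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmropls)
```

`nmropls` implements the differential-analysis workflow for two-group
1H-NMR tissue metabolomics: a labelled synthetic cohort generator,
spectral bucketing with constant-sum normalization, per-bin Student's
t-tests with Storey–Tibshirani q-values, single-response OPLS-DA, a
hold-out classification check, metabolite aggregation through a
chemical-shift library, and Fisher over-representation. This vignette
records the models, the defaults and why they were chosen, the
numerical conventions, and the limitations a user should know about.

## The synthetic cohort generator

Real tissue studies of this design rarely deposit raw spectra, so the
package ships a simulator whose output has known ground truth. A
metabolite template is a set of resonances (centre ppm, relative
intensity proportional to proton count and concentration weighting,
half-width); a spectrum is the sum over metabolites and peaks of
`amplitude × relative_intensity × L(ppm)`, with `L` a **unit-area
Lorentzian** — the natural NMR lineshape; half-width default 0.005 ppm,
a typical tissue MAS linewidth. Gaussian i.i.d. noise is added per grid
point; an optional smooth low-order baseline is off by default.
Acquisition physics (FID, phasing, water suppression, spinning
sidebands) is deliberately out of scope.

Defaults mirror the motivating study design: **12 treated vs 11
control** samples; ~18 brain metabolites with shifts hand-curated from
standard reference spectra, anchored at the lactate CH3 doublet at
1.325 ppm (the conventional tissue reference); planted treated/control
fold changes equal to the reported cortex values (0.84–1.15, e.g. NAA
1.13, GABA 1.09, taurine 0.88, citrate 0.84), applied multiplicatively
to the treated group's amplitudes; metabolites without a reported
change stay at fold change 1. Base amplitudes are free parameters of
the simulator (absolute concentrations are not reported in such
studies); the defaults are rough relative brain concentrations (NAA,
creatine and glutamate dominant). The grid default is 0–10 ppm at
0.0005 ppm, i.e. 20 points per 0.01-ppm bucket. The default
`noise_sd = 5` gives clean, high-SNR spectra; `noise_sd_for_bin_snr()`
calibrates the noise so that the **median** affected-bin group
difference equals a chosen multiple (default 3) of the bucket-level
noise standard deviation — the median, not the maximum, because
interval-edge bins carry little Lorentzian mass and a max-based
calibration would drown every weaker metabolite.

With zero noise the treated/control bucket ratio over an isolated
metabolite's support equals its planted fold change to machine
precision; with several metabolites the infinite Lorentzian tails leak
a little intensity everywhere, so ratios agree with the planted values
only to about 1% — the tests check both regimes at their respective
tolerances.

What the simulator does **not** emulate: peak position jitter (pH- and
ion-dependent shift changes), correlated baselines, macromolecule
background, inter-animal biological variance beyond the additive noise,
and peak-shape distortions. Passing tests therefore certify the
statistical machinery on well-behaved spectra, not robustness to
misaligned or badly phased real data.

## Bucketing and normalization

Buckets are half-open intervals `[b, b + 0.01)` ppm anchored at the
range's lower bound (the convention is arbitrary; half-open tiling
guarantees each grid point lands in exactly one bucket, which the test
suite verifies against an exhaustive point-assignment loop). The bucket
value is the plain sum of point intensities — a rectangular integral up
to the constant grid step, which the subsequent normalization cancels.
A bucket partially covered by an exclusion interval is dropped whole;
partial-area reweighting would introduce an arbitrary convention for no
statistical gain. The five default exclusions (0–0.6, 1.1–1.23,
3.62–3.7, 4.54–5.0, 8.3–20 ppm) remove signal-free ends, ethanol
contamination and residual water. Bin counts are a function of the
configured range — on the default 0–10 ppm range the pipeline retains
703 bins; nothing in the package assumes a particular count.
Constant-sum normalization divides each row by its own total (target
constant 1; any other constant would cancel in every downstream
ratio and scaled quantity).

## Univariate screen

Pooled-variance two-sided Student's t per bin (the classical test for
this design; Welch is not used), computed on normalized, unscaled
values — scaling to unit variance is a multivariate-modelling device
and would distort fold changes. Degenerate bins (zero pooled variance)
get t = 0, p = 1 when means agree and are flagged `degenerate` with
p = 0 when they differ. The q-value machinery follows the published
estimator: π̂₀(λ) on the λ grid 0.05–0.95 (step 0.05), cubic smoothing
spline (df = 3) evaluated at λ = 0.95, clamped to (0, 1]; a fixed-λ
mode exists for exact hand-checkable arithmetic. With π̂₀ = 1 the
step-up q-values coincide with Benjamini–Hochberg adjusted p-values,
which the tests assert to 1e-12.

## OPLS-DA

The single-y orthogonal projections to latent structures algorithm:
with X unit-variance scaled and y the centred 1/2 class coding, the
predictive weight is w = Xᵀy/‖Xᵀy‖; for each orthogonal component the
X-loading p = Xᵀt/tᵀt is stripped of its predictive part,
w_o ∝ p − (wᵀp)w, and X is deflated by t_o p_oᵀ. One orthogonal
component is the default (the usual choice for a two-class bucket
table); the count is configurable. Orthogonal scores are uncorrelated
with y *exactly* by construction, and the model's predictions with
1 predictive + k orthogonal components are identical to those of plain
NIPALS PLS1 with k + 1 components — the suite asserts this
equivalence to 1e-8 against an independent PLS1 implementation, which
pins down the fitting algebra far more strongly than any single
numeric fixture.

R²X is the fraction of scaled-X sum of squares captured by all
components; R²Y the fraction of centred-y sum of squares explained by
the predictive component. Q² = 1 − PRESS/SSY under 7-fold
cross-validation (the chemometrics convention; the fold count is
configurable), with folds assigned by a seeded shuffle followed by
round-robin, and the **whole** model — unit-variance scaling included —
refit on each training split, so no test-fold information leaks into
scaling. Q² never exceeds R²Y in practice but, being a PRESS statistic
at n = 23, its null distribution is wide: on pure-noise data the mean
across seeds sits well below 0 while individual realizations
occasionally reach ≈ 0.2, so null behaviour should be judged on an
ensemble, not a single fit.

VIP uses the standard PLS formula, in which orthogonal components
carry zero response variance, so it collapses to √p·|w_j| and
Σ VIP² = p identically (asserted to 1e-9). Back-scaled coefficients
multiply the overall first-component coefficient vector by each bin's
original standard deviation, restoring spectral appearance; colour
values rescale VIP to [0, 1] between its minimum and maximum (defined
as 0.5 everywhere if all VIPs tie). Under the 1/2 coding an elevated
bin predicts a *lower* score, so negative back-scaled coefficients
mean "up in treated"; the sign is reported as fitted rather than
flipped for display, to stay consistent with `predict()`.

Zero-variance bins are dropped at scaling and recorded; prediction
matches columns by name, so new data may include or omit dropped
columns. A score exactly at the classification cutoff (1.5) is
assigned to control — the rule is "treated if strictly below".

## Hold-out validation

Three held-out samples per class, four repeats, full refit per repeat.
The four test sets are drawn independently per repeat (each repeat a
seeded draw without replacement); a disjoint-partition mode exists but
errors when a class is too small for it — with 11 controls, four
disjoint draws of three are impossible, which is precisely why
independent draws are the default. The report's average is
100·Σcorrect/Σtested.

## Annotation and enrichment

Selection is strict (`q < 0.2` **or** `VIP > 1.5`); boundary values are
not selected. A bin maps to every library metabolite whose half-open
interval contains its centre; overlaps are reported as ambiguity
rather than broken by a tie-rule (the shipped library deliberately
keeps the real acetate/GABA overlap near 1.9 ppm). Metabolite fold
change is computed over the metabolite's *selected* bins (per sample:
sum the bins; then ratio of group means); with a fixed bin set this
equals the ratio of summed group means, so the two natural phrasings
coincide (asserted to 1e-12). Fisher enrichment takes an explicit
universe file — there is no hidden knowledge base, so every p-value is
auditable; the right-tailed hypergeometric p equals exhaustive
enumeration to 1e-12 and no multiple-testing adjustment is applied to
pathway p-values (a BH column is emitted as an extra). The shipped
pathway sets and universe are synthetic stand-ins (named accordingly)
for a proprietary commercial knowledge base; published coverage ratios
are recomputed from printed hit counts and pathway sizes only.

## Known limitations

**Constant-sum normalization is compositional.** Relative bucket
values must sum to one, so a net increase in total planted signal
reappears as an apparent *decrease* spread over every unchanged
metabolite. The default fold-change set is net-up (total treated
signal +0.9% under the default amplitudes), and at a calibrated
per-bin SNR of 3 the largest unchanged peaks (creatine, glutamate,
lactate, choline) acquire apparent effects of the same order as the
median planted per-bin effect — they are then selected and reported,
inflating the false-metabolite rate (≈25% of reported metabolites
against the raw-amplitude ground truth, measured over 50 seeded
cohorts) even though the bin-level q-values control what they claim to
control: discoveries against the *normalized-space* null. No amplitude
configuration removes this for an unbalanced fold-change set (equal
amplitudes give +1.9%). Interestingly, the directions such an artifact
produces (unlisted high-concentration metabolites drifting down) match
the decreased trends the motivating study itself displayed for
creatine, choline and glutamate. Users comparing recovered metabolites
to a raw-concentration ground truth should expect this effect;
probabilistic-quotient or reference-peak normalization would trade it
for different artifacts and is out of scope here.

**Other limitations.** The VIP variant of commercial OPLS software is
undocumented and may blend orthogonal contributions; the standard
formula is used. The q-value smoother needs a reasonable p-value count
(hundreds) to estimate π₀ stably and errors when π̂₀ ≤ 0. Shift-library
intervals are a best-effort curation and user-editable; real spectra
need peak alignment before this pipeline, which the package does not
provide.

## Test problem sizes

The calibration checks run at deliberately chosen sizes: null
calibration pools 200 cohorts of 12 vs 11 samples over a 0.6–4.2 ppm
range at a 0.001-ppm grid step (339 retained bins — enough bins for a
tight binomial band at modest cost); recovery runs 50 cohorts on the
full default grid; the OPLS/PLS equivalence sweeps 20 random problems
with n = 10–30 and p = 6–50. All stochastic checks fix their seeds.
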