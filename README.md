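# nmropls

Differential analysis of two-group 1H-NMR metabolomics studies, built
around the workflow used for tissue CPMG spectra of treated-vs-control
animal cohorts (the motivating design: brain tissue of 12 MK-801
treated vs 11 control rats): spectral bucketing, constant-sum
normalization, per-bin univariate testing with false-discovery-rate
q-values, OPLS-DA chemometrics, a hold-out classification check,
metabolite-level fold-change aggregation, and pathway
over-representation. A synthetic-cohort simulator with known ground
truth stands in for raw spectra, which such studies rarely deposit, so
every stage is testable end to end.

## What the package computes

**Bucketing.** Each spectrum (ppm, intensity) is reduced to 0.01-ppm
buckets tiling the analysis range in half-open intervals; buckets
touching exclusion regions (0–0.6 no signal, 1.1–1.23 and 3.62–3.7
ethanol contamination, 4.54–5.0 water, 8.3–20 no signal) are dropped
whole. Rows are normalized to constant sum: x_ij ← x_ij / Σ_j x_ij.

**Univariate screen.** Per bin, a two-sided pooled-variance Student's
t-test (df = n₁+n₂−2) on the normalized values; p-values map to
Storey–Tibshirani q-values with π₀ estimated by
π̂₀(λ) = #{p > λ}/(m(1−λ)) smoothed over λ ∈ {0.05,…,0.95} by a cubic
spline, and q₍ᵢ₎ = min_{j≥i} π̂₀ · m · p₍ⱼ₎ / j.

**OPLS-DA.** Classes coded 1 (treated) / 2 (control), response
centred; unit-variance scaling of X; the single-y orthogonal
projections to latent structures model fitted by NIPALS: predictive
weight w ∝ Xᵀy, each orthogonal component w_o ∝ p − (wᵀp)w with X
deflated by t_o p_oᵀ. Reported: R²X, R²Y, 7-fold cross-validated
Q² = 1 − PRESS/SSY (scaling refit on training folds only),
VIP_j = √p·|w_j| (so mean VIP² = 1), and back-scaled coefficients
(coefficients × original bin standard deviation) coloured by
min–max-rescaled VIP for spectral display. Under the 1/2 coding a
*negative* back-scaled coefficient means the bin is elevated in the
treated group.

**Validation.** Four repeats of: hold out three samples per class,
refit scaling + OPLS-DA on the rest, predict held-out scores, call
treated when score < 1.5; report per-repeat correct counts and the
average percentage correct.

**Annotation.** Bins with q < 0.2 or VIP > 1.5 (strict) are selected,
assigned to every shift-library metabolite whose interval contains the
bin centre (overlaps flagged as ambiguous, e.g. acetate/GABA near
1.9 ppm), and each metabolite's fold change is the treated/control
ratio of the mean sum of its selected bins.

**Enrichment.** Right-tailed hypergeometric (one-sided Fisher's exact)
p-value per pathway against an explicit universe, with the coverage
ratio hits/|pathway ∩ universe|.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort
(`Rscript analysis/01_simulate.R` … `07_enrich.R`, outputs under
`results/`). The same pipeline in one call:

```r
library(nmropls)
coh <- simulate_cohort(sim_config(seed = 101))  # 12 treated vs 11 control
res <- run_analyze(coh$spectra, seed = 101)
res$model
#> OPLS-DA model: 1 predictive + 1 orthogonal component(s), p = 703
#>   R2X = 0.251  R2Y = 1.000  Q2 = 0.964  (7-fold CV)
#>   class coding: treated = 1, control = 2
res$cv_report$average_percent_correct
#> [1] 100
head(res$metabolite_table, 5)
```

yields the Table-1-style metabolite table (from
`results/metabolite_table.tsv`):

```
metabolite       kegg_id n_bins avg_fold_change direction ambiguous
NAA              C01042  11     1.119           up        FALSE
Scyllo-inositol  C06153   3     1.113           up        FALSE
L-Alanine        C00041   3     1.109           up        FALSE
L-Aspartate      C00049   9     1.103           up        FALSE
Acetate          C00033   4     1.101           up        TRUE
```

The 703 bins come from the 0–10 ppm range at 0.01 ppm minus the five
exclusions; the planted cortex-style fold changes (0.84–1.15) are
recovered with the right directions, the Q² of 0.96 reflects the clean
default noise level, and the `ambiguous` flag on acetate marks its
shared 1.9-ppm interval with GABA. `fisher_enrichment()` on the
reported KEGG IDs against the shipped synthetic pathway sets ranks
glutamate metabolism first (5/7 covered, p = 0.016).

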