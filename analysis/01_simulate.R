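#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 12 MK-801-style treated vs 11
# control spectra over 0-10 ppm, with the cortex fold-change set
# planted on the treated group. Writes one two-column spectrum file per
# sample plus manifest and ground truth under results/cohort/.

library(nmropls)

seed <- 101
cfg <- sim_config(seed = seed)
coh <- simulate_cohort(cfg)
write_cohort(coh, "results/cohort")

cat(sprintf("Simulated %d treated + %d control spectra (seed %d)\n",
            cfg$n_treated, cfg$n_control, seed))
cat(sprintf("Planted effects on %d metabolites (fold changes %.2f-%.2f)\n",
            length(coh$truth$affected),
            min(cfg$fold_changes), max(cfg$fold_changes)))
cat("Wrote results/cohort/ (spectra, manifest.tsv, ground_truth.tsv)\n")
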