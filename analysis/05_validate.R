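#!/usr/bin/env Rscript
# Hold-out classification validation: four repeats, three held-out
# samples per class, OPLS-DA refit from scratch on each training split,
# class called by the 1.5 cutoff on the 1/2 coding scale. Writes
# results/holdout_report.tsv.

library(nmropls)

tab <- read_bucket_table("results/bucket_table.tsv")
rep_ <- holdout_classification(tab, test_per_class = 3, repeats = 4,
                               cutoff = 1.5, seed = 101)
print(rep_)
nmropls:::write_table_commented(
  rep_$repeats, "results/holdout_report.tsv",
  sprintf("average_percent_correct: %.6f", rep_$average_percent_correct))
cat("Wrote results/holdout_report.tsv\n")
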