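# Small in-code fixtures shared across test files.

# A minimal two-metabolite template set with widely separated peaks.
tiny_templates <- function() {
  data.frame(
    metabolite = c("A", "A", "B"),
    kegg_id = c("C00001", "C00001", "C00002"),
    center_ppm = c(0.9, 1.0, 7.1),
    relative_intensity = c(2, 1, 3),
    halfwidth_ppm = 0.005,
    stringsAsFactors = FALSE)
}

# One isolated single-peak metabolite, for exact-arithmetic checks.
single_template <- function(center = 1.325) {
  data.frame(metabolite = "GABA", kegg_id = "C00334",
             center_ppm = center, relative_intensity = 1,
             halfwidth_ppm = 0.005, stringsAsFactors = FALSE)
}

# Fast small cohort: few metabolites, coarse grid, small noise.
quick_config <- function(seed = 1, fold_changes = c(B = 1.5),
                         noise_sd = 0, n_treated = 5, n_control = 4) {
  sim_config(n_treated = n_treated, n_control = n_control,
             templates = tiny_templates(), fold_changes = fold_changes,
             base_amplitudes = c(A = 2, B = 1), noise_sd = noise_sd,
             grid = c(0.5, 7.5, 0.001), seed = seed)
}

quick_grid <- function() {
  bucket_grid(width = 0.01, range = c(0.5, 7.5), exclusions = list())
}

# Random bucket-table-shaped matrix with a planted class difference.
random_labelled_matrix <- function(seed, n = 14, p = 20, effect = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  g <- rep(c("treated", "control"), length.out = n)
  if (effect > 0) X[g == "treated", 1:3] <- X[g == "treated", 1:3] + effect
  list(X = X, groups = g)
}

# In-memory spectrum constructor mirroring the package's internal shape.
make_spectrum <- function(id, ppm, intensity, group = "treated") {
  structure(list(sample_id = id, ppm = ppm, intensity = intensity,
                 group = group), class = "nmr_spectrum")
}
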