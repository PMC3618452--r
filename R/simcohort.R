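#' Read a metabolite peak template table
#'
#' A template table describes, per metabolite, the resonances used to
#' render synthetic 1H-NMR spectra: chemical-shift centre, relative
#' intensity (proportional to proton count times concentration weight)
#' and Lorentzian half-width at half-maximum.
#'
#' @param path Path to a tab-separated file with columns `metabolite`,
#'   `kegg_id`, `center_ppm`, `relative_intensity`, `halfwidth_ppm`
#'   (one row per peak; several rows per metabolite).
#' @return A data frame of peaks with one row per resonance.
#' @export
read_metabolite_peaks <- function(path) {
  df <- read_table_commented(path)
  need <- c("metabolite", "kegg_id", "center_ppm", "relative_intensity",
            "halfwidth_ppm")
  if (!all(need %in% names(df))) {
    stop_fmt("peak template file %s lacks columns: %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  validate_templates(df)
  df
}

#' Default brain-tissue metabolite templates
#'
#' Fifteen-plus metabolites commonly resolved in CPMG spectra of brain
#' tissue (lactate, NAA, creatine, acetate, GABA, choline compounds,
#' amino acids, inositols, Krebs-cycle acids), with shifts hand-curated
#' from standard reference spectra; the lactate CH3 doublet is anchored
#' at 1.325 ppm, the conventional chemical-shift reference in tissue
#' spectra. The shipped file is plain text and user-editable.
#'
#' @return A data frame of peaks (see [read_metabolite_peaks()]).
#' @export
default_metabolite_templates <- function() {
  read_metabolite_peaks(system.file("extdata", "metabolite_peaks.tsv",
                                    package = "nmropls", mustWork = TRUE))
}

validate_templates <- function(templates) {
  if (!nrow(templates)) stop_fmt("template table has no peaks")
  if (any(!is.finite(templates$center_ppm)) ||
      any(templates$center_ppm < 0 | templates$center_ppm > 10)) {
    stop_fmt("peak centres must be finite and within 0-10 ppm")
  }
  if (any(!is.finite(templates$relative_intensity)) ||
      any(templates$relative_intensity <= 0)) {
    stop_fmt("relative intensities must be finite and positive")
  }
  if (any(!is.finite(templates$halfwidth_ppm)) ||
      any(templates$halfwidth_ppm <= 0)) {
    stop_fmt("peak halfwidths must be finite and positive")
  }
  invisible(templates)
}

#' Default base amplitudes (relative concentrations)
#'
#' Rough relative tissue concentrations for the default templates, on an
#' arbitrary scale (NAA, creatine and glutamate dominate brain spectra;
#' scyllo-inositol and valine are minor). Absolute concentrations are
#' free parameters of the simulator.
#'
#' @return Named numeric vector, one entry per default metabolite.
#' @export
default_base_amplitudes <- function() {
  c("NAA" = 10, "Creatine" = 8, "L-Glutamate" = 9, "Myo-inositol" = 6,
    "Taurine" = 6, "Lactate" = 6, "L-Glutamine" = 4, "L-Aspartate" = 2.5,
    "GABA" = 2, "Choline" = 1.5, "Phosphorylcholine" = 1.5,
    "L-Alanine" = 1.5, "L-Serine" = 1.2, "Acetate" = 1,
    "Succinate" = 0.8, "Citrate" = 0.8, "Scyllo-inositol" = 0.6,
    "L-Valine" = 0.5)
}

#' Default planted fold changes (cortex study design)
#'
#' The multiplicative treated-vs-control effects planted by default,
#' matching the reported cortex metabolite fold changes of the MK-801
#' rat study (magnitudes 0.84-1.15); metabolites without a reported
#' change carry fold change 1 (unaffected).
#'
#' @return Named numeric vector of fold changes applied to the treated
#'   group's amplitudes.
#' @export
default_fold_changes <- function() {
  c("Scyllo-inositol" = 1.15, "Acetate" = 1.13, "L-Aspartate" = 1.13,
    "NAA" = 1.13, "L-Alanine" = 1.12, "GABA" = 1.09, "L-Serine" = 1.07,
    "Succinate" = 1.07, "L-Glutamine" = 0.92, "Myo-inositol" = 0.92,
    "Phosphorylcholine" = 0.90, "Taurine" = 0.88, "Citrate" = 0.84)
}

#' Simulation configuration for a synthetic NMR cohort
#'
#' Bundles the study design (group sizes mirroring the 12 treated vs 11
#' control animals), the spectral templates, planted multiplicative
#' group effects, noise level and acquisition grid into a validated
#' configuration object.
#'
#' @param n_treated,n_control Group sizes (defaults 12 and 11).
#' @param templates Peak template data frame
#'   (default [default_metabolite_templates()]).
#' @param fold_changes Named vector of fold changes applied to treated
#'   samples' amplitudes; metabolites omitted get 1. `NULL` plants the
#'   defaults of [default_fold_changes()]; use `numeric(0)` for a null
#'   cohort with no effect.
#' @param base_amplitudes Named vector of per-metabolite amplitudes;
#'   defaults to [default_base_amplitudes()] for known metabolites and 1
#'   otherwise.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise
#'   per grid point (default 5, giving clean high-SNR spectra).
#' @param grid Numeric `c(min_ppm, max_ppm, step)`; default 0-10 ppm at
#'   0.0005 ppm (20 points per 0.01-ppm bucket).
#' @param baseline_amplitude Amplitude of a smooth low-order polynomial
#'   baseline added to every spectrum (default 0, off).
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_treated = 12, n_control = 11,
                       templates = default_metabolite_templates(),
                       fold_changes = NULL,
                       base_amplitudes = NULL,
                       noise_sd = 5,
                       grid = c(0, 10, 5e-4),
                       baseline_amplitude = 0,
                       seed = 1) {
  validate_templates(templates)
  mets <- unique(templates$metabolite)
  if (is.null(fold_changes)) {
    fold_changes <- default_fold_changes()
    fold_changes <- fold_changes[names(fold_changes) %in% mets]
  }
  if (length(fold_changes)) {
    unknown <- setdiff(names(fold_changes), mets)
    if (length(unknown)) {
      stop_fmt("fold changes name unknown metabolites: %s",
               paste(unknown, collapse = ", "))
    }
    if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
      stop_fmt("fold changes must be finite and strictly positive")
    }
  }
  if (is.null(base_amplitudes)) {
    defaults <- default_base_amplitudes()
    base_amplitudes <- stats::setNames(
      ifelse(mets %in% names(defaults), defaults[mets], 1), mets)
  }
  unknown <- setdiff(names(base_amplitudes), mets)
  if (length(unknown)) {
    stop_fmt("amplitudes name unknown metabolites: %s",
             paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(base_amplitudes)) || any(base_amplitudes <= 0)) {
    stop_fmt("base amplitudes must be finite and strictly positive")
  }
  missing_amp <- setdiff(mets, names(base_amplitudes))
  if (length(missing_amp)) {
    base_amplitudes <- c(base_amplitudes,
                         stats::setNames(rep(1, length(missing_amp)),
                                         missing_amp))
  }
  if (n_treated < 2 || n_control < 2) {
    stop_fmt("each group needs at least 2 samples")
  }
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2]) {
    stop_fmt("grid must be c(min_ppm, max_ppm, step) with step > 0, min < max")
  }
  if (noise_sd < 0 || baseline_amplitude < 0) {
    stop_fmt("noise_sd and baseline_amplitude must be non-negative")
  }
  structure(list(n_treated = as.integer(n_treated),
                 n_control = as.integer(n_control),
                 templates = templates,
                 fold_changes = fold_changes,
                 base_amplitudes = base_amplitudes,
                 noise_sd = noise_sd,
                 grid = as.numeric(grid),
                 baseline_amplitude = baseline_amplitude,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ppm_grid <- function(grid) {
  seq(grid[1], grid[2], by = grid[3])
}

#' Render a noise-free spectrum from metabolite templates
#'
#' Evaluates, at every grid point, the sum over metabolites and peaks of
#' `amplitude * relative_intensity * L(ppm; center, halfwidth)` where
#' `L` is a unit-area Lorentzian (the natural NMR lineshape), plus an
#' optional smooth polynomial baseline.
#'
#' @param templates Peak template data frame.
#' @param amplitudes Named numeric vector keyed by metabolite name.
#' @param grid `c(min_ppm, max_ppm, step)`.
#' @param baseline_amplitude Height scale of a fixed smooth baseline
#'   (default 0).
#' @return A list with `ppm` and `intensity` vectors.
#' @export
render_spectrum <- function(templates, amplitudes, grid = c(0, 10, 5e-4),
                            baseline_amplitude = 0) {
  ppm <- ppm_grid(grid)
  y <- numeric(length(ppm))
  if (nrow(templates)) {
    unknown <- setdiff(names(amplitudes), unique(templates$metabolite))
    if (length(unknown)) {
      stop_fmt("amplitudes name unknown metabolites: %s",
               paste(unknown, collapse = ", "))
    }
    amp <- amplitudes[templates$metabolite]
    keep <- !is.na(amp)
    for (i in which(keep)) {
      g <- templates$halfwidth_ppm[i]
      h <- amp[i] * templates$relative_intensity[i] * (g / pi)
      y <- y + h / ((ppm - templates$center_ppm[i])^2 + g^2)
    }
  }
  if (baseline_amplitude > 0) {
    u <- (ppm - grid[1]) / (grid[2] - grid[1])
    y <- y + baseline_amplitude * (0.5 + u * (1 - u))
  }
  list(ppm = ppm, intensity = y)
}

new_spectrum <- function(sample_id, ppm, intensity, group = NA_character_) {
  structure(list(sample_id = sample_id, ppm = ppm,
                 intensity = intensity, group = group),
            class = "nmr_spectrum")
}

#' Simulate a labelled synthetic NMR cohort
#'
#' Draws `n_treated + n_control` spectra: control samples use the base
#' amplitudes, treated samples use base amplitudes multiplied by the
#' planted fold changes; i.i.d. Gaussian noise of sd `noise_sd` is added
#' at every grid point. The returned ground truth records the planted
#' effects so downstream recovery can be scored.
#'
#' @param config A [sim_config()] object.
#' @return A list with `spectra` (list of spectra, class `nmr_spectrum`,
#'   treated first), `manifest` (sample_id, group data frame) and
#'   `truth` (`affected` metabolite names and `fold_changes`, the full
#'   per-metabolite true fold-change vector).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mets <- unique(config$templates$metabolite)
  fc <- stats::setNames(rep(1, length(mets)), mets)
  if (length(config$fold_changes)) {
    fc[names(config$fold_changes)] <- config$fold_changes
  }
  amp_control <- config$base_amplitudes[mets]
  amp_treated <- amp_control * fc[mets]
  base_t <- render_spectrum(config$templates, amp_treated, config$grid,
                            config$baseline_amplitude)
  base_c <- render_spectrum(config$templates, amp_control, config$grid,
                            config$baseline_amplitude)
  n <- config$n_treated + config$n_control
  ids <- sprintf("%s%02d", rep(c("T", "C"), c(config$n_treated,
                                              config$n_control)),
                 c(seq_len(config$n_treated), seq_len(config$n_control)))
  groups <- rep(c("treated", "control"),
                c(config$n_treated, config$n_control))
  spectra <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      base <- if (groups[i] == "treated") base_t else base_c
      eps <- if (config$noise_sd > 0) {
        stats::rnorm(length(base$ppm), 0, config$noise_sd)
      } else 0
      new_spectrum(ids[i], base$ppm, base$intensity + eps, groups[i])
    })
  })
  list(spectra = spectra,
       manifest = data.frame(sample_id = ids, group = groups,
                             stringsAsFactors = FALSE),
       truth = list(affected = names(fc)[fc != 1],
                    fold_changes = fc))
}

#' Calibrate noise to a target per-bin signal-to-noise ratio
#'
#' Renders the noise-free group-mean spectra of a configuration, buckets
#' them, and returns the grid-point noise sd at which the median
#' absolute treated-control bucket difference over the affected
#' metabolites' library intervals equals `snr` times the bucket-level
#' noise sd (bucket noise sd is `sqrt(points per bucket)` times the
#' grid-point sd).
#'
#' @param config A [sim_config()] with planted effects.
#' @param snr Target per-bin SNR for the median affected bin (default 3).
#' @param grid Bucketing grid (default [bucket_grid()]).
#' @param library Shift library used to locate affected bins (default
#'   [default_shift_library()]).
#' @return Grid-point noise sd (numeric scalar).
#' @export
noise_sd_for_bin_snr <- function(config, snr = 3, grid = bucket_grid(),
                                 library = default_shift_library()) {
  stopifnot(inherits(config, "sim_config"), snr > 0)
  mets <- unique(config$templates$metabolite)
  fc <- stats::setNames(rep(1, length(mets)), mets)
  if (length(config$fold_changes)) fc[names(config$fold_changes)] <- config$fold_changes
  affected <- names(fc)[fc != 1]
  if (!length(affected)) stop_fmt("configuration plants no effects")
  amp_control <- config$base_amplitudes[mets]
  st <- render_spectrum(config$templates, amp_control * fc[mets], config$grid)
  sc <- render_spectrum(config$templates, amp_control, config$grid)
  bt <- bin_spectrum(new_spectrum("t", st$ppm, st$intensity), grid)
  bc <- bin_spectrum(new_spectrum("c", sc$ppm, sc$intensity), grid)
  lib <- library[library$metabolite %in% affected, , drop = FALSE]
  in_lib <- vapply(bt$bin_centers, function(p) {
    any(p >= lib$lo_ppm & p < lib$hi_ppm)
  }, logical(1))
  delta <- abs(bt$bin_values - bc$bin_values)[in_lib]
  delta <- delta[delta > 0]
  if (!length(delta)) stop_fmt("no affected bins found in the shift library")
  pts_per_bucket <- grid$width / config$grid[3]
  stats::median(delta) / (snr * sqrt(pts_per_bucket))
}

#' Write a simulated cohort to per-sample text files
#'
#' One two-column (ppm, intensity) tab-separated file per sample, plus
#' `manifest.tsv` (sample_id, group) and `ground_truth.tsv` (metabolite,
#' true fold change, affected flag).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cohort$spectra) {
    utils::write.table(
      data.frame(ppm = sp$ppm, intensity = sp$intensity),
      file.path(dir, paste0(sp$sample_id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_table_commented(cohort$manifest, file.path(dir, "manifest.tsv"))
  gt <- data.frame(metabolite = names(cohort$truth$fold_changes),
                   true_fold_change = unname(cohort$truth$fold_changes),
                   affected = names(cohort$truth$fold_changes) %in%
                     cohort$truth$affected)
  write_table_commented(gt, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
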