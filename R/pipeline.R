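#' Run the full differential-analysis pipeline
#'
#' Orchestrates bucketing, constant-sum normalization, per-bin t-tests
#' with Storey q-values, OPLS-DA with VIP and back-scaled coefficients,
#' hold-out classification validation, bin selection and metabolite
#' aggregation, and (when pathway definitions are supplied) Fisher
#' over-representation. One global seed drives cross-validation fold
#' assignment and hold-out draws via deterministically derived
#' per-stage seeds, so identical inputs give byte-identical outputs.
#'
#' @param spectra List of `nmr_spectrum` objects, or a directory of
#'   per-sample spectra with a `manifest.tsv` (see [read_cohort()]).
#' @param grid A [bucket_grid()].
#' @param shift_library Shift library data frame (default
#'   [default_shift_library()]).
#' @param pathways Named list of pathway member sets, or `NULL` to skip
#'   enrichment.
#' @param universe Universe ID vector (required with `pathways`).
#' @param treated,control Group labels.
#' @param n_orth Orthogonal components (default 1).
#' @param cv_folds Q2 cross-validation folds (default 7).
#' @param q_cut,vip_cut Bin selection thresholds (defaults 0.2, 1.5).
#' @param test_per_class,repeats,cutoff Hold-out validation parameters
#'   (defaults 3, 4, 1.5).
#' @param seed Global seed (default 1).
#' @param out_dir If non-NULL, write every result table plus a JSON run
#'   manifest there.
#' @return List with `bucket_table` (normalized), `bin_stats`, `model`,
#'   `backscaled`, `cv_report`, `metabolite_table`, `assignment`
#'   (including unassigned bins), `enrichment` (or NULL) and `params`.
#' @export
run_analyze <- function(spectra, grid = bucket_grid(),
                        shift_library = default_shift_library(),
                        pathways = NULL, universe = NULL,
                        treated = "treated", control = "control",
                        n_orth = 1, cv_folds = 7,
                        q_cut = 0.2, vip_cut = 1.5,
                        test_per_class = 3, repeats = 4, cutoff = 1.5,
                        seed = 1, out_dir = NULL) {
  if (is.character(spectra)) spectra <- read_cohort(spectra)
  stage <- "bucketing"
  res <- tryCatch({
    table <- normalize_constant_sum(build_bucket_table(spectra, grid))
    stage <- "univariate statistics"
    stats <- add_qvalues(student_t_per_bin(table, treated, control))
    stage <- "OPLS-DA"
    model <- fit_oplsda(uv_scale(table), table$groups, treated = treated,
                        n_orth = n_orth, cv_folds = cv_folds,
                        seed = derive_seed(seed, 1L))
    stats$vip <- model$vip[match(format_ppm(stats$bin_ppm),
                                 colnames(model$scaler$values))]
    stats$vip[is.na(stats$vip)] <- 0  # zero-variance bins carry no weight
    back <- backscaled_coefficients(model)
    stage <- "hold-out validation"
    cv <- holdout_classification(table, treated, control,
                                 test_per_class = test_per_class,
                                 repeats = repeats, cutoff = cutoff,
                                 n_orth = n_orth,
                                 seed = derive_seed(seed, 2L))
    stage <- "bin selection and annotation"
    stats <- select_bins(stats, q_cut = q_cut, vip_cut = vip_cut)
    asg <- assign_bins(stats, shift_library)
    met <- metabolite_fold_change(table, asg$assignments, treated, control)
    stage <- "pathway enrichment"
    enr <- NULL
    if (!is.null(pathways)) {
      if (is.null(universe)) stop_fmt("pathways supplied without a universe")
      if (nrow(met)) {
        enr <- fisher_enrichment(unique(met$kegg_id), pathways, universe)
      }
    }
    list(bucket_table = table, bin_stats = stats, model = model,
         backscaled = back, cv_report = cv, metabolite_table = met,
         assignment = asg, enrichment = enr,
         params = list(grid_width = grid$width, grid_range = grid$range,
                       n_orth = n_orth, cv_folds = cv_folds,
                       q_cut = q_cut, vip_cut = vip_cut,
                       test_per_class = test_per_class, repeats = repeats,
                       cutoff = cutoff, seed = seed))
  }, error = function(e) {
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

# Write every pipeline product as commented plain-text tables plus a
# machine-readable JSON manifest of inputs, parameters and versions.
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmt <- sprintf("seed: %d", res$params$seed)
  write_bucket_table(res$bucket_table,
                     file.path(out_dir, "bucket_table.tsv"), cmt)
  stats <- res$bin_stats
  stats_out <- data.frame(bin_ppm = stats$bin_ppm,
                          direction = stats$direction,
                          fold_change = stats$fold_change,
                          p_value = stats$p_value,
                          q_value = stats$q_value,
                          vip = stats$vip,
                          selected = stats$selected)
  stats_out <- stats_out[order(-stats_out$bin_ppm), , drop = FALSE]
  write_table_commented(stats_out, file.path(out_dir, "bin_stats.tsv"), cmt)
  write_table_commented(res$metabolite_table,
                        file.path(out_dir, "metabolite_table.tsv"), cmt)
  write_table_commented(res$backscaled,
                        file.path(out_dir, "backscaled_coefficients.tsv"),
                        cmt)
  model_summary <- data.frame(r2x = res$model$r2x, r2y = res$model$r2y,
                              q2 = res$model$q2,
                              n_orth = res$model$n_orth,
                              cv_folds = res$model$cv_folds)
  write_table_commented(model_summary,
                        file.path(out_dir, "model_summary.tsv"), cmt)
  write_table_commented(res$cv_report$repeats,
                        file.path(out_dir, "holdout_report.tsv"),
                        c(cmt, sprintf("average_percent_correct: %.6f",
                                       res$cv_report$average_percent_correct)))
  if (!is.null(res$enrichment)) {
    write_table_commented(res$enrichment,
                          file.path(out_dir, "enrichment.tsv"), cmt)
  }
  manifest <- c(res$params,
                list(n_samples = length(res$bucket_table$sample_ids),
                     n_bins = length(res$bucket_table$bin_centers),
                     package_version =
                       as.character(utils::packageVersion("nmropls"))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
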