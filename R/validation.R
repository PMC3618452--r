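#' Hold-out classification validation of OPLS-DA predictivity
#'
#' Repeats the following seeded procedure: draw `test_per_class`
#' samples from each class as a test set; unit-variance scale and fit
#' an OPLS-DA model on the remaining samples only (no information from
#' the test set enters scaling or fitting); predict the held-out
#' samples' continuous class scores; call a sample treated when its
#' score falls strictly below the cutoff midway between the class
#' codes (1 for treated, 2 for control), control otherwise — a score
#' exactly at the cutoff goes to control. The report carries per-repeat
#' correct counts and the average percentage of correct classification,
#' `100 * sum(correct) / sum(tested)`.
#'
#' By default the four test sets are drawn independently (each repeat
#' its own seeded draw without replacement); `disjoint = TRUE` instead
#' partitions one shuffled sequence into non-overlapping test sets,
#' which requires `repeats * test_per_class` samples per class.
#'
#' @param table A normalized `bucket_table`.
#' @param treated,control Group labels.
#' @param test_per_class Held-out samples per class per repeat
#'   (default 3).
#' @param repeats Number of repeats (default 4).
#' @param cutoff Classification cutoff on the 1/2 coding scale
#'   (default 1.5).
#' @param n_orth Orthogonal components for each refit (default 1).
#' @param seed Seed governing all draws (default 1).
#' @param disjoint Draw non-overlapping test sets (default FALSE).
#' @param keep_models Keep each repeat's fitted model in the report
#'   (default FALSE; used for leakage auditing).
#' @return Object of class `cv_report`: `repeats` data frame
#'   (`repeat_id`, `test_ids`, `n_correct`, `n_test`),
#'   `average_percent_correct`, `cutoff`, `seed`, and optionally
#'   `models`.
#' @export
holdout_classification <- function(table, treated = "treated",
                                   control = "control",
                                   test_per_class = 3, repeats = 4,
                                   cutoff = 1.5, n_orth = 1, seed = 1,
                                   disjoint = FALSE,
                                   keep_models = FALSE) {
  stopifnot(inherits(table, "bucket_table"))
  idx_t <- which(table$groups == treated)
  idx_c <- which(table$groups == control)
  if (length(idx_t) <= test_per_class || length(idx_c) <= test_per_class) {
    stop_fmt("each class must have more than %d samples", test_per_class)
  }
  if (disjoint &&
      (length(idx_t) < repeats * test_per_class ||
       length(idx_c) < repeats * test_per_class)) {
    stop_fmt("disjoint mode needs %d samples per class",
             repeats * test_per_class)
  }
  draws <- if (disjoint) {
    perm_t <- with_seed(derive_seed(seed, 11L), sample(idx_t))
    perm_c <- with_seed(derive_seed(seed, 12L), sample(idx_c))
    lapply(seq_len(repeats), function(r) {
      block <- seq.int((r - 1) * test_per_class + 1, r * test_per_class)
      c(perm_t[block], perm_c[block])
    })
  } else {
    lapply(seq_len(repeats), function(r) {
      c(with_seed(derive_seed(seed, 100L + r),
                  sample(idx_t, test_per_class)),
        with_seed(derive_seed(seed, 200L + r),
                  sample(idx_c, test_per_class)))
    })
  }
  models <- vector("list", repeats)
  rows <- lapply(seq_len(repeats), function(r) {
    test <- draws[[r]]
    train_tab <- subset_bucket_table(table, setdiff(seq_along(table$groups),
                                                    test))
    fit <- fit_oplsda(uv_scale(train_tab), train_tab$groups,
                      treated = treated, n_orth = n_orth, cv_folds = 0)
    if (keep_models) models[[r]] <<- fit
    scores <- predict(fit, table$values[test, , drop = FALSE])
    predicted <- ifelse(scores < cutoff, treated, control)
    data.frame(repeat_id = r,
               test_ids = paste(table$sample_ids[test], collapse = ","),
               n_correct = sum(predicted == table$groups[test]),
               n_test = length(test), stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  out <- list(repeats = rep_df,
              average_percent_correct =
                100 * sum(rep_df$n_correct) / sum(rep_df$n_test),
              cutoff = cutoff, seed = seed,
              test_draws = draws)
  if (keep_models) out$models <- models
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("hold-out classification: %d repeats, cutoff %.2f\n",
              nrow(x$repeats), x$cutoff))
  for (i in seq_len(nrow(x$repeats))) {
    cat(sprintf("  repeat %d: %d/%d correct\n", i,
                x$repeats$n_correct[i], x$repeats$n_test[i]))
  }
  cat(sprintf("  average correct classification: %.1f%%\n",
              x$average_percent_correct))
  invisible(x)
}
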