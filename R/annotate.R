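#' Read a chemical-shift library
#'
#' A shift library maps metabolites (with KEGG compound IDs) to the
#' half-open ppm intervals `[lo, hi)` their resonances occupy; several
#' rows per metabolite are allowed and intervals of different
#' metabolites may overlap (overlaps are reported as ambiguity, not
#' hidden).
#'
#' @param path Tab-separated file with columns `metabolite`, `kegg_id`,
#'   `lo_ppm`, `hi_ppm`.
#' @return Data frame with those columns.
#' @export
read_shift_library <- function(path) {
  df <- read_table_commented(path)
  need <- c("metabolite", "kegg_id", "lo_ppm", "hi_ppm")
  if (!all(need %in% names(df))) {
    stop_fmt("shift library %s lacks columns: %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$lo_ppm >= df$hi_ppm)) {
    stop_fmt("shift library has intervals with lo >= hi")
  }
  df
}

#' Default shift library matching the default templates
#'
#' Hand-curated intervals around the default metabolite resonances; the
#' acetate and GABA intervals deliberately overlap around 1.9 ppm, a
#' genuine assignment ambiguity in tissue spectra. The shipped file is
#' plain text and user-editable.
#'
#' @return Data frame (see [read_shift_library()]).
#' @export
default_shift_library <- function() {
  read_shift_library(system.file("extdata", "shift_library.tsv",
                                 package = "nmropls", mustWork = TRUE))
}

#' Select treatment-related bins
#'
#' A bin is selected when its q-value is strictly below `q_cut` or its
#' VIP strictly above `vip_cut` (strict inequalities: q = `q_cut` or
#' VIP = `vip_cut` exactly is not selected).
#'
#' @param stats `bin_stats` with `q_value` and `vip` filled.
#' @param q_cut q-value threshold (default 0.2).
#' @param vip_cut VIP threshold (default 1.5).
#' @return The table with the `selected` flag filled.
#' @export
select_bins <- function(stats, q_cut = 0.2, vip_cut = 1.5) {
  if (anyNA(stats$q_value) || anyNA(stats$vip)) {
    stop_fmt("q_value and vip must be filled before selection")
  }
  stats$selected <- stats$q_value < q_cut | stats$vip > vip_cut
  stats
}

#' Assign selected bins to metabolites via a shift library
#'
#' A bin maps to every metabolite whose interval contains its centre
#' (half-open `[lo, hi)`); bins inside several metabolites' intervals
#' are flagged ambiguous and contribute to each, and bins matching no
#' interval are reported separately.
#'
#' @param stats `bin_stats` with `selected` filled (only selected bins
#'   are assigned).
#' @param library Shift library data frame (default
#'   [default_shift_library()]).
#' @return List with `assignments` (data frame `metabolite`, `kegg_id`,
#'   `bin_ppm`, `ambiguous`) and `unassigned` (ppm vector).
#' @export
assign_bins <- function(stats, library = default_shift_library()) {
  if (!nrow(library)) stop_fmt("shift library is empty")
  sel <- stats[which(stats$selected), , drop = FALSE]
  rows <- list(); unassigned <- numeric(0)
  for (ppm in sel$bin_ppm) {
    hit <- which(library$lo_ppm <= ppm & ppm < library$hi_ppm)
    mets <- unique(library$metabolite[hit])
    if (!length(mets)) {
      unassigned <- c(unassigned, ppm)
    } else {
      amb <- length(mets) > 1
      for (m in mets) {
        kegg <- library$kegg_id[library$metabolite == m][1]
        rows[[length(rows) + 1L]] <-
          data.frame(metabolite = m, kegg_id = kegg, bin_ppm = ppm,
                     ambiguous = amb, stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), kegg_id = character(0),
               bin_ppm = numeric(0), ambiguous = logical(0))
  list(assignments = assignments, unassigned = unassigned)
}

#' Metabolite-level average fold changes
#'
#' For each metabolite, sums its assigned (discriminant) bins per
#' sample and reports the fold change as the ratio of the treated-group
#' mean of that sum to the control-group mean; with fixed bin sets this
#' equals the ratio of summed group bin means, so the two textual
#' routes ("average of summed bins" vs "sum of averaged bins")
#' coincide. Direction is up exactly when the fold change exceeds 1.
#'
#' @param table Normalized `bucket_table`.
#' @param assignments Assignment data frame from [assign_bins()].
#' @param treated,control Group labels.
#' @return Data frame `metabolite`, `kegg_id`, `n_bins`,
#'   `avg_fold_change`, `direction`, `ambiguous`, sorted by descending
#'   fold change.
#' @export
metabolite_fold_change <- function(table, assignments,
                                   treated = "treated",
                                   control = "control") {
  stopifnot(inherits(table, "bucket_table"))
  if (!nrow(assignments)) {
    return(data.frame(metabolite = character(0), kegg_id = character(0),
                      n_bins = integer(0), avg_fold_change = numeric(0),
                      direction = character(0), ambiguous = logical(0)))
  }
  i1 <- table$groups == treated
  i2 <- table$groups == control
  out <- lapply(split(assignments, assignments$metabolite), function(a) {
    cols <- match(format_ppm(a$bin_ppm), colnames(table$values))
    if (anyNA(cols)) {
      stop_fmt("metabolite %s: assigned bin not present in bucket table",
               a$metabolite[1])
    }
    sums <- rowSums(table$values[, cols, drop = FALSE])
    mc <- mean(sums[i2])
    if (mc <= 0) {
      stop_fmt("metabolite %s: control group mean is not positive",
               a$metabolite[1])
    }
    fc <- mean(sums[i1]) / mc
    data.frame(metabolite = a$metabolite[1], kegg_id = a$kegg_id[1],
               n_bins = nrow(a), avg_fold_change = fc,
               direction = ifelse(fc > 1, "up", "down"),
               ambiguous = any(a$ambiguous), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$avg_fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}
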