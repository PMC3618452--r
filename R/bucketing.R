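#' Read a one-sample spectrum from two-column delimited text
#'
#' Expects two numeric columns (ppm, intensity), whitespace- or
#' tab-separated, with an optional header line. Rows are re-sorted to
#' ascending ppm internally; files written in the descending NMR
#' convention parse to the same spectrum.
#'
#' @param path File path.
#' @param sample_id Sample identifier (default: file name without
#'   extension).
#' @param group Optional group label.
#' @return An object of class `nmr_spectrum` with fields `sample_id`,
#'   `ppm` (ascending), `intensity`, `group`.
#' @export
read_spectrum <- function(path, sample_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop_fmt("spectrum file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  first_data <- 1L
  parse_row <- function(line) {
    suppressWarnings(as.numeric(strsplit(trimws(line), "[\t, ]+")[[1]]))
  }
  if (length(lines) && any(is.na(parse_row(lines[1])))) {
    first_data <- 2L  # header line
  }
  if (length(lines) < first_data + 1L) {
    stop_fmt("spectrum %s: fewer than 2 data points", path)
  }
  ppm <- numeric(0); intensity <- numeric(0)
  for (i in seq(first_data, length(lines))) {
    v <- parse_row(lines[i])
    if (length(v) < 2 || anyNA(v[1:2])) {
      stop_fmt("spectrum %s: non-numeric or short row at line %d: '%s'",
               path, i, lines[i])
    }
    ppm <- c(ppm, v[1]); intensity <- c(intensity, v[2])
  }
  ord <- order(ppm)
  ppm <- ppm[ord]; intensity <- intensity[ord]
  if (anyDuplicated(ppm)) {
    dup <- ppm[duplicated(ppm)][1]
    stop_fmt("spectrum %s: duplicate ppm value %g", path, dup)
  }
  if (any(!is.finite(intensity))) {
    stop_fmt("spectrum %s: non-finite intensities", path)
  }
  new_spectrum(sample_id, ppm, intensity, group)
}

#' Read a cohort of spectra listed in a manifest
#'
#' @param dir Directory holding `<sample_id>.tsv` spectrum files.
#' @param manifest Data frame with `sample_id` and `group` columns, or a
#'   path to such a table (default `<dir>/manifest.tsv`).
#' @return List of `nmr_spectrum` objects.
#' @export
read_cohort <- function(dir, manifest = file.path(dir, "manifest.tsv")) {
  if (is.character(manifest)) manifest <- read_table_commented(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_spectrum(file.path(dir, paste0(manifest$sample_id[i], ".tsv")),
                  manifest$sample_id[i], manifest$group[i])
  })
}

#' Default excluded chemical-shift regions
#'
#' The five standard exclusions for this assay: 0-0.6 ppm (no signal),
#' 1.1-1.23 and 3.62-3.7 ppm (ethanol contamination from tool
#' disinfection), 4.54-5.0 ppm (residual water) and 8.3-20 ppm (no
#' signal).
#'
#' @return List of `c(lo, hi)` ppm intervals.
#' @export
default_exclusions <- function() {
  list(c(0, 0.6), c(1.1, 1.23), c(3.62, 3.7), c(4.54, 5.0), c(8.3, 20))
}

#' Define a bucketing grid
#'
#' Buckets tile `[lo, hi)` in half-open intervals `[b, b + width)`
#' anchored at the range lower bound. Any bucket intersecting an
#' exclusion interval is dropped whole.
#'
#' @param width Bucket width in ppm (default 0.01).
#' @param range `c(lo, hi)` analysis range in ppm (default 0-10).
#' @param exclusions List of `c(lo, hi)` intervals (default
#'   [default_exclusions()]).
#' @return An object of class `bucket_grid`.
#' @export
bucket_grid <- function(width = 0.01, range = c(0, 10),
                        exclusions = default_exclusions()) {
  if (width <= 0) stop_fmt("bucket width must be positive")
  if (length(range) != 2 || range[1] >= range[2]) {
    stop_fmt("range must be c(lo, hi) with lo < hi")
  }
  for (e in exclusions) {
    if (length(e) != 2 || e[1] >= e[2]) {
      stop_fmt("each exclusion must be c(lo, hi) with lo < hi")
    }
  }
  structure(list(width = width, range = as.numeric(range),
                 exclusions = exclusions),
            class = "bucket_grid")
}

# Bucket bookkeeping: lower edges, retained flags.
grid_buckets <- function(grid) {
  nb <- floor((grid$range[2] - grid$range[1]) / grid$width + 1e-9)
  lo <- grid$range[1] + (seq_len(nb) - 1L) * grid$width
  hi <- lo + grid$width
  keep <- rep(TRUE, nb)
  eps <- 1e-9 * grid$width
  for (e in grid$exclusions) {
    keep <- keep & !(lo < e[2] - eps & e[1] < hi - eps)
  }
  list(lo = lo, hi = hi, centers = lo + grid$width / 2, keep = keep)
}

#' Bucket a spectrum
#'
#' Each retained grid point is assigned to exactly one half-open bucket
#' `[b, b + width)`; the bucket value is the plain sum of the point
#' intensities inside it (a rectangular integral up to the constant grid
#' step, which constant-sum normalization later cancels). Buckets
#' intersecting any exclusion are dropped entirely.
#'
#' @param spec An `nmr_spectrum`.
#' @param grid A [bucket_grid()].
#' @return List with `bin_centers` (ascending ppm) and `bin_values`.
#' @export
bin_spectrum <- function(spec, grid) {
  stopifnot(inherits(grid, "bucket_grid"))
  b <- grid_buckets(grid)
  if (!any(b$keep)) {
    stop_fmt("bucketing grid retains no buckets (range fully excluded)")
  }
  idx <- floor((spec$ppm - grid$range[1]) / grid$width + 1e-9) + 1L
  inside <- idx >= 1L & idx <= length(b$lo) & spec$ppm >= grid$range[1]
  vals <- numeric(length(b$lo))
  if (any(inside)) {
    agg <- rowsum(spec$intensity[inside], idx[inside])
    vals[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(bin_centers = b$centers[b$keep], bin_values = vals[b$keep])
}

#' Build a samples-by-bins bucket table
#'
#' @param specs List of `nmr_spectrum` objects sharing a ppm grid.
#' @param grid A [bucket_grid()].
#' @return An object of class `bucket_table`: fields `sample_ids`,
#'   `groups`, `bin_centers` (ascending ppm; write functions emit the
#'   descending NMR convention), `values` (n_samples x n_bins matrix)
#'   and `normalized` flag.
#' @export
build_bucket_table <- function(specs, grid = bucket_grid()) {
  binned <- lapply(specs, bin_spectrum, grid = grid)
  centers <- binned[[1]]$bin_centers
  values <- do.call(rbind, lapply(binned, `[[`, "bin_values"))
  colnames(values) <- format_ppm(centers)
  structure(list(
    sample_ids = vapply(specs, `[[`, character(1), "sample_id"),
    groups = vapply(specs, function(s) as.character(s$group %||% NA),
                    character(1)),
    bin_centers = centers,
    values = values,
    normalized = FALSE,
    grid = grid), class = "bucket_table")
}

format_ppm <- function(x) sprintf("%.3f", x)

#' Constant-sum normalization
#'
#' Divides each sample's bucket row by its own total so every row sums
#' to one, making profiles comparable across samples regardless of
#' overall signal intensity.
#'
#' @param table A `bucket_table`.
#' @return The table with `values` row-normalized and `normalized = TRUE`.
#' @export
normalize_constant_sum <- function(table) {
  stopifnot(inherits(table, "bucket_table"))
  totals <- rowSums(table$values)
  bad <- which(totals <= 0)
  if (length(bad)) {
    stop_fmt("sample(s) with non-positive total intensity: %s",
             paste(table$sample_ids[bad], collapse = ", "))
  }
  table$values <- table$values / totals
  table$normalized <- TRUE
  table
}

subset_bucket_table <- function(table, rows) {
  table$sample_ids <- table$sample_ids[rows]
  table$groups <- table$groups[rows]
  table$values <- table$values[rows, , drop = FALSE]
  table
}

#' Write / read a bucket table as delimited text
#'
#' Columns: `sample_id`, `group`, then one column per bin headed by its
#' centre ppm in descending order (NMR convention).
#'
#' @param table A `bucket_table`.
#' @param path Output path.
#' @param comments Optional comment lines for the header.
#' @return `write_bucket_table`: the path, invisibly.
#' @export
write_bucket_table <- function(table, path, comments = character()) {
  ord <- order(table$bin_centers, decreasing = TRUE)
  df <- data.frame(sample_id = table$sample_ids, group = table$groups,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- table$values[, ord, drop = FALSE]
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  write_table_commented(df, path,
                        c(comments,
                          sprintf("normalized: %s", table$normalized)))
}

#' @rdname write_bucket_table
#' @param normalized Normalization flag to record on the read table
#'   (default: taken from the file's comment header if present).
#' @return `read_bucket_table`: a `bucket_table`.
#' @export
read_bucket_table <- function(path, normalized = NULL) {
  header <- grep("^# ", readLines(path, n = 20L), value = TRUE)
  if (is.null(normalized)) {
    normalized <- any(grepl("normalized: TRUE", header))
  }
  df <- read_table_commented(path)
  centers <- as.numeric(names(df)[-(1:2)])
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  ord <- order(centers)
  centers <- centers[ord]
  values <- values[, ord, drop = FALSE]
  colnames(values) <- format_ppm(centers)
  structure(list(sample_ids = df$sample_id, groups = df$group,
                 bin_centers = centers, values = values,
                 normalized = normalized, grid = NULL),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("bucket_table: %d samples x %d bins (%.3f-%.3f ppm), %s\n",
              nrow(x$values), ncol(x$values), min(x$bin_centers),
              max(x$bin_centers),
              if (x$normalized) "constant-sum normalized" else "raw"))
  invisible(x)
}
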