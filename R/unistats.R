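#' Per-bin two-sample Student's t-tests
#'
#' Two-sided pooled-variance t-test for every bucket, computed on the
#' constant-sum normalized (unscaled) values, with the treated group in
#' the numerator of the fold change. Degenerate bins (zero pooled
#' variance) get t = 0, p = 1 when the group means are equal, and p = 0
#' with `degenerate = TRUE` when they differ.
#'
#' @param table A normalized `bucket_table`.
#' @param treated,control Group labels (defaults "treated", "control").
#' @return A data frame of per-bin statistics (class also
#'   `bin_stats`): `bin_ppm`, `mean_treated`, `mean_control`, `t_stat`,
#'   `p_value`, `q_value` (NA until filled), `vip` (NA until filled),
#'   `fold_change`, `direction`, `selected` (NA until filled),
#'   `degenerate`.
#' @export
student_t_per_bin <- function(table, treated = "treated",
                              control = "control") {
  stopifnot(inherits(table, "bucket_table"))
  if (!table$normalized) {
    stop_fmt("bucket table must be constant-sum normalized before testing")
  }
  i1 <- which(table$groups == treated)
  i2 <- which(table$groups == control)
  if (length(i1) < 2 || length(i2) < 2) {
    stop_fmt("each group needs at least 2 samples (found %d treated, %d control)",
             length(i1), length(i2))
  }
  x1 <- table$values[i1, , drop = FALSE]
  x2 <- table$values[i2, , drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  degenerate <- se == 0 & m1 != m2
  tt[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  p[se == 0 & m1 == m2] <- 1
  p[degenerate] <- 0
  tt[degenerate] <- Inf * sign(m1 - m2)[degenerate]
  fc <- m1 / m2
  out <- data.frame(
    bin_ppm = table$bin_centers,
    mean_treated = m1, mean_control = m2,
    t_stat = tt, p_value = p,
    q_value = NA_real_, vip = NA_real_,
    fold_change = fc,
    direction = ifelse(fc > 1, "up", "down"),
    selected = NA,
    degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("bin_stats", "data.frame")
  out
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 and maps each p-value to a q-value,
#' the estimated false discovery rate incurred when calling that test
#' (and all smaller p) significant. `pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda))`; the smoother method fits a cubic smoothing spline
#' (df = 3) of pi0 over the lambda grid and evaluates it at the largest
#' lambda, clamped to (0, 1]; the fixed-lambda method uses a single
#' lambda. q-values are the step-up minima `min_{j >= i} pi0 * m *
#' p_(j) / j`, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param method `"smoother"` (default) or `"fixed"`.
#' @param lambda Lambda grid (smoother; default `seq(0.05, 0.95, 0.05)`)
#'   or single value (fixed; default 0.5).
#' @return List of class `qvalue_result`: `pvalues`, `qvalues`, `pi0`,
#'   `lambda_grid`, `method`.
#' @export
storey_qvalues <- function(pvalues, method = c("smoother", "fixed"),
                           lambda = NULL) {
  method <- match.arg(method)
  m <- length(pvalues)
  if (m < 1) stop_fmt("need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  if (is.null(lambda)) {
    lambda <- if (method == "smoother") seq(0.05, 0.95, by = 0.05) else 0.5
  }
  pi0_hat <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                    numeric(1))
  if (method == "smoother") {
    if (length(lambda) < 4) {
      stop_fmt("smoother method needs a lambda grid of at least 4 values")
    }
    fit <- stats::smooth.spline(lambda, pi0_hat, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  } else {
    if (length(lambda) != 1) {
      stop_fmt("fixed method takes a single lambda")
    }
    pi0 <- pi0_hat
  }
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) {
    stop_fmt("estimated pi0 <= 0; use method = 'fixed' with a smaller lambda")
  }
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  qvalues <- numeric(m)
  qvalues[ord] <- q_sorted
  structure(list(pvalues = pvalues, qvalues = qvalues, pi0 = pi0,
                 lambda_grid = lambda, method = method),
            class = "qvalue_result")
}

#' Attach q-values to a bin statistics table
#'
#' @param stats A `bin_stats` data frame from [student_t_per_bin()].
#' @param ... Passed to [storey_qvalues()].
#' @return The table with `q_value` filled; the `qvalue_result` is
#'   attached as attribute `"qvalue"`.
#' @export
add_qvalues <- function(stats, ...) {
  qr <- storey_qvalues(stats$p_value, ...)
  stats$q_value <- qr$qvalues
  attr(stats, "qvalue") <- qr
  stats
}
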