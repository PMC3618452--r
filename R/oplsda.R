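#' Unit-variance (autoscaling) of a bucket table or matrix
#'
#' Mean-centres every column and divides by its standard deviation
#' (n - 1 denominator) so low- and high-intensity buckets contribute
#' equally to the multivariate model. Zero-variance columns are dropped
#' and recorded.
#'
#' @param x A `bucket_table` or a numeric matrix with column names.
#' @return Object of class `uv_scaled`: `values` (scaled matrix),
#'   `center`, `scale` (named by retained column), `dropped` (names of
#'   zero-variance columns), `bin_centers` (ppm of retained columns
#'   when available).
#' @export
uv_scale <- function(x) {
  bin_centers <- NULL
  if (inherits(x, "bucket_table")) {
    bin_centers <- x$bin_centers
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  if (nrow(x) < 2) stop_fmt("unit-variance scaling needs n >= 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop_fmt("all columns have zero variance")
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  sds[keep], "/")
  structure(list(values = scaled,
                 center = ctr[keep], scale = sds[keep],
                 dropped = colnames(x)[!keep],
                 bin_centers = if (!is.null(bin_centers))
                   bin_centers[keep] else NULL),
            class = "uv_scaled")
}

# Scale new raw data with training parameters; columns matched by name,
# columns dropped at training are ignored, extras tolerated.
apply_scaling <- function(scaled, newdata) {
  if (inherits(newdata, "bucket_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  cols <- colnames(scaled$values)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(cols) + length(scaled$dropped)) {
      stop_fmt("new data has %d columns; training data had %d",
               ncol(newdata), length(cols) + length(scaled$dropped))
    }
    colnames(newdata) <- c(cols, scaled$dropped)[seq_len(ncol(newdata))]
  }
  missing <- setdiff(cols, colnames(newdata))
  if (length(missing)) {
    stop_fmt("new data lacks %d training column(s), e.g. %s",
             length(missing), missing[1])
  }
  nd <- newdata[, cols, drop = FALSE]
  sweep(sweep(nd, 2, scaled$center), 2, scaled$scale, "/")
}

# Trygg & Wold single-y O-PLS core on a centred X and centred y.
opls_core <- function(X, y, n_orth) {
  p_dim <- ncol(X)
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-300) stop_fmt("X carries no covariance with y")
  w <- w / nw
  W_o <- P_o <- matrix(0, p_dim, 0)
  T_o <- matrix(0, nrow(X), 0)
  ssx_comp <- 0
  Xi <- X
  for (i in seq_len(n_orth)) {
    t_ <- drop(Xi %*% w)
    p_ <- drop(crossprod(Xi, t_)) / sum(t_^2)
    w_o <- p_ - drop(crossprod(w, p_)) * w
    n_o <- sqrt(sum(w_o^2))
    if (n_o < 1e-10) {
      stop_fmt("requested %d orthogonal components exceeds the rank of X",
               n_orth)
    }
    w_o <- w_o / n_o
    t_o <- drop(Xi %*% w_o)
    p_o <- drop(crossprod(Xi, t_o)) / sum(t_o^2)
    Xi <- Xi - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    ssx_comp <- ssx_comp + sum(t_o^2) * sum(p_o^2)
  }
  t_pred <- drop(Xi %*% w)
  p_load <- drop(crossprod(Xi, t_pred)) / sum(t_pred^2)
  c_load <- sum(y * t_pred) / sum(t_pred^2)
  fitted <- t_pred * c_load
  ssx_comp <- ssx_comp + sum(t_pred^2) * sum(p_load^2)
  # overall linear coefficient in the scaled space:
  # y_hat = c * X (I - w_o1 p_o1') ... (I - w_ok p_ok') w
  v <- w
  for (i in rev(seq_len(ncol(W_o)))) {
    v <- v - W_o[, i] * sum(P_o[, i] * v)
  }
  list(w = w, W_o = W_o, P_o = P_o, T_o = T_o,
       t_pred = t_pred, p_load = p_load, c_load = c_load,
       fitted = fitted, coef = c_load * v,
       r2x = ssx_comp / sum(X^2),
       r2y = 1 - sum((y - fitted)^2) / sum(y^2))
}

opls_core_predict <- function(core, Xs) {
  Xi <- Xs
  for (i in seq_len(ncol(core$W_o))) {
    t_o <- drop(Xi %*% core$W_o[, i])
    Xi <- Xi - tcrossprod(t_o, core$P_o[, i])
  }
  drop(Xi %*% core$w) * core$c_load
}

# Seeded shuffle + round-robin fold assignment (the CV convention used
# for Q2 throughout the package).
cv_fold_ids <- function(n, k, seed) {
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  folds
}

#' Fit a single-response OPLS-DA model
#'
#' Codes the two classes 1 (treated) / 2 (control), centres the coded
#' response, and fits the single-y orthogonal projections to latent
#' structures model by NIPALS: the predictive weight is the normalized
#' covariance direction of X with y; each orthogonal component removes
#' the part of the X loading orthogonal to the predictive weight, and
#' the predictive component is refit on the filtered X. Reports R2X
#' (X sum of squares explained by predictive + orthogonal components),
#' R2Y, and a k-fold cross-validated Q2 = 1 - PRESS/SSY in which every
#' fold refits the whole model — unit-variance scaling included — on
#' the training samples only.
#'
#' @param x A `uv_scaled` object (see [uv_scale()]).
#' @param groups Character/factor vector of class labels, length n.
#' @param treated Label coded 1 (default "treated"); the other observed
#'   label is coded 2.
#' @param n_orth Number of orthogonal components (default 1).
#' @param cv_folds Folds for Q2 cross-validation (default 7, the usual
#'   chemometrics convention); 0 skips Q2.
#' @param seed Seed for the CV fold shuffle (default 1).
#' @return Object of class `opls_model` with predictive weight `w`
#'   (unit norm), scores/loadings, orthogonal `W_o`/`P_o`/`T_o`,
#'   `r2x`, `r2y`, `q2`, `vip`, scaled-space `coefficients`, the
#'   training scaler and the y coding.
#' @export
fit_oplsda <- function(x, groups, treated = "treated", n_orth = 1,
                       cv_folds = 7, seed = 1) {
  stopifnot(inherits(x, "uv_scaled"))
  X <- x$values
  n <- nrow(X)
  groups <- as.character(groups)
  if (length(groups) != n) stop_fmt("groups length does not match X rows")
  lev <- unique(groups)
  if (length(lev) != 2) stop_fmt("exactly two classes required")
  if (!treated %in% lev) stop_fmt("treated label '%s' not found", treated)
  control <- setdiff(lev, treated)
  y_coded <- ifelse(groups == treated, 1, 2)
  ybar <- mean(y_coded)
  y <- y_coded - ybar
  if (n_orth < 0) stop_fmt("n_orth must be >= 0")
  if (cv_folds != 0 && (cv_folds < 2 || cv_folds > n)) {
    stop_fmt("cv_folds must be 0 or between 2 and n")
  }
  core <- opls_core(X, y, n_orth)
  p_dim <- ncol(X)
  vip <- sqrt(p_dim) * abs(core$w)
  q2 <- NA_real_
  if (cv_folds >= 2) {
    raw <- sweep(sweep(X, 2, x$scale, "*"), 2, x$center, "+")
    folds <- cv_fold_ids(n, cv_folds, seed)
    press <- 0
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      if (all(test) || !any(test)) next
      sc_tr <- uv_scale(raw[!test, , drop = FALSE])
      ctr_y <- mean(y_coded[!test])
      core_f <- opls_core(sc_tr$values, y_coded[!test] - ctr_y, n_orth)
      pred <- opls_core_predict(core_f,
                                apply_scaling(sc_tr,
                                              raw[test, , drop = FALSE])) +
        ctr_y
      press <- press + sum((y_coded[test] - pred)^2)
    }
    q2 <- 1 - press / sum(y^2)
  }
  structure(list(w = core$w, t_pred = core$t_pred, p_load = core$p_load,
                 c_load = core$c_load,
                 W_o = core$W_o, P_o = core$P_o, T_o = core$T_o,
                 coefficients = core$coef,
                 r2x = core$r2x, r2y = core$r2y, q2 = q2,
                 vip = vip, n_orth = n_orth, cv_folds = cv_folds,
                 seed = seed, scaler = x, y_mean = ybar,
                 y_coding = stats::setNames(c(1, 2), c(treated, control)),
                 fitted = core$fitted + ybar,
                 groups = groups),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: 1 predictive + %d orthogonal component(s), p = %d\n",
    x$n_orth, length(x$w)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %s  (%d-fold CV)\n",
              x$r2x, x$r2y,
              ifelse(is.na(x$q2), "NA", sprintf("%.3f", x$q2)),
              x$cv_folds))
  cat(sprintf("  class coding: %s = 1, %s = 2\n",
              names(x$y_coding)[1], names(x$y_coding)[2]))
  invisible(x)
}

#' Predict class scores for new samples
#'
#' Applies the training unit-variance scaling to the new (raw) data,
#' removes the orthogonal variation with the training orthogonal
#' weights/loadings, and projects onto the predictive component. Scores
#' are on the 1 (treated) / 2 (control) coding scale.
#'
#' @param object A fitted `opls_model`.
#' @param newdata Raw matrix or `bucket_table` with named columns
#'   matching the training data (columns dropped at scaling may be
#'   present or absent).
#' @param ... Unused.
#' @return Numeric vector of continuous class scores.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(object$scaler, newdata)
  opls_core_predict(object, Xs) + object$y_mean
}

#' Variable importance for the projection (VIP)
#'
#' Standard PLS VIP, `VIP_j = sqrt(p * sum_a (w_aj/|w_a|)^2 * SSY_a /
#' sum_a SSY_a)`; orthogonal components explain no response variance
#' (SSY_a = 0), so for a single-predictive-component OPLS model the
#' formula collapses to `sqrt(p) * |w_j|` for the unit-norm predictive
#' weight, and `mean(VIP^2) = 1` identically.
#'
#' @param model A fitted `opls_model`.
#' @return Numeric vector of VIP values, one per retained variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  model$vip
}

#' Back-scaled coefficients for spectral-style display
#'
#' Multiplies the first-component model coefficients by each variable's
#' original standard deviation, restoring the spectral appearance of
#' the loadings; each bin is coloured by its VIP value rescaled to
#' [0, 1] between the minimum and maximum VIP.
#'
#' @param model A fitted `opls_model` (fitted on a `uv_scale`d bucket
#'   table so bin ppm values are available).
#' @return Data frame with `ppm`, `back_coef`, `vip`, `color_value`.
#' @export
backscaled_coefficients <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  sds <- model$scaler$scale
  back <- model$coefficients * sds
  v <- model$vip
  rng <- range(v)
  color <- if (diff(rng) <= 0) rep(0.5, length(v)) else
    (v - rng[1]) / diff(rng)
  ppm <- model$scaler$bin_centers
  if (is.null(ppm)) {
    ppm <- suppressWarnings(as.numeric(names(sds)))
    if (anyNA(ppm)) ppm <- seq_along(sds)
  }
  data.frame(ppm = ppm, back_coef = unname(back), vip = unname(v),
             color_value = unname(color), row.names = NULL)
}
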