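test_that("unit-variance scaling centres, scales and drops constant columns", {
  two <- matrix(c(1, 3), 2, 1, dimnames = list(NULL, "a"))
  sc2 <- uv_scale(two)
  expect_equal(unname(sc2$values[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-4)

  set.seed(5)
  X <- cbind(a = rnorm(8), b = rnorm(8), c = rep(2, 8))
  sc <- uv_scale(X)
  expect_equal(sc$dropped, "c")
  expect_true(all(abs(colMeans(sc$values)) < 1e-9))
  expect_true(all(abs(apply(sc$values, 2, sd) - 1) < 1e-9))
  # idempotence: rescaling a scaled matrix changes nothing
  expect_equal(unname(uv_scale(sc$values)$values), unname(sc$values),
               tolerance = 1e-9)
  expect_error(uv_scale(matrix(1, 5, 2)), "zero variance")
})

test_that("a perfect predictor column yields R2Y = 1 and exact predictions", {
  set.seed(6)
  n <- 12
  g <- rep(c("treated", "control"), each = 6)
  y <- ifelse(g == "treated", 1, 2)
  yc <- y - mean(y)
  # noise columns orthogonalized against y so they carry no covariance
  # with the response (pure noise in the model's sense)
  noise <- matrix(rnorm(n * 5), n, 5)
  noise <- noise - yc %*% crossprod(yc, noise) / sum(yc^2)
  X <- cbind(sig = yc, noise)
  colnames(X) <- c("sig", paste0("n", 1:5))
  m <- fit_oplsda(uv_scale(X), g, n_orth = 0, cv_folds = 0)
  expect_equal(m$r2y, 1, tolerance = 1e-9)
  expect_equal(unname(predict(m, X)), y, tolerance = 1e-9)
})

test_that("orthogonal scores are uncorrelated with the response by construction", {
  for (s in 1:4) {
    d <- random_labelled_matrix(s, n = 16, p = 12, effect = 1)
    m <- fit_oplsda(uv_scale(d$X), d$groups, n_orth = 2, cv_folds = 0)
    y <- ifelse(d$groups == "treated", 1, 2)
    yc <- y - mean(y)
    for (j in seq_len(ncol(m$T_o))) {
      expect_lt(abs(cor(m$T_o[, j], yc)), 1e-8)
    }
    expect_equal(sqrt(sum(m$w^2)), 1, tolerance = 1e-12)
  }
})

test_that("OPLS with 1+k components predicts identically to PLS1 with k+1", {
  d <- random_labelled_matrix(99, n = 10, p = 6)
  sc <- uv_scale(d$X)
  y <- ifelse(d$groups == "treated", 1, 2)
  f <- pls1_fit(sc$values, y - mean(y), 2)
  m <- fit_oplsda(sc, d$groups, n_orth = 1, cv_folds = 0)
  expect_lt(max(abs(predict(m, d$X) -
                    (pls1_predict(f, sc$values) + mean(y)))), 1e-8)
})

test_that("R2X reaches 1 when components exhaust the rank of X", {
  set.seed(17)
  X <- matrix(rnorm(6 * 3), 6, 3)
  colnames(X) <- paste0("v", 1:3)
  g <- rep(c("treated", "control"), each = 3)
  # centred scaled X has rank 3; 2 orthogonal + 1 predictive spans it
  m <- fit_oplsda(uv_scale(X), g, n_orth = 2, cv_folds = 0)
  expect_equal(m$r2x, 1, tolerance = 1e-6)
  expect_error(fit_oplsda(uv_scale(X), g, n_orth = 5, cv_folds = 0),
               "rank")
})

test_that("VIP satisfies its algebraic identity and degenerate cases", {
  # single variable: VIP = 1
  set.seed(23)
  g <- rep(c("treated", "control"), each = 4)
  X1 <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "a"))
  m1 <- fit_oplsda(uv_scale(X1), g, n_orth = 0, cv_folds = 0)
  expect_equal(unname(vip(m1)), 1, tolerance = 1e-12)

  # identical informative columns share VIP = 1
  base <- ifelse(g == "treated", 1, -1) + rnorm(8, sd = 0.1)
  Xs <- matrix(base, 8, 4, dimnames = list(NULL, paste0("v", 1:4)))
  Xs <- Xs + matrix(rnorm(32, sd = 1e-6), 8, 4)  # break exact collinearity
  ms <- fit_oplsda(uv_scale(Xs), g, n_orth = 0, cv_folds = 0)
  expect_true(all(abs(vip(ms) - 1) < 1e-3))

  # mean(VIP^2) = 1 on arbitrary fitted models
  for (s in 1:5) {
    d <- random_labelled_matrix(30 + s, n = 15, p = 11, effect = s %% 2)
    m <- fit_oplsda(uv_scale(d$X), d$groups, n_orth = 1, cv_folds = 0)
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-9)
  }
})

test_that("back-scaled coefficients restore spectral scale and VIP colouring", {
  d <- random_labelled_matrix(55, n = 14, p = 9, effect = 2)
  sc <- uv_scale(d$X)
  m <- fit_oplsda(sc, d$groups, n_orth = 1, cv_folds = 0)
  bc <- backscaled_coefficients(m)
  expect_equal(bc$back_coef, unname(m$coefficients * sc$scale),
               tolerance = 1e-12)
  expect_equal(bc$color_value[which.min(bc$vip)], 0)
  expect_equal(bc$color_value[which.max(bc$vip)], 1)
  expect_true(all(bc$color_value >= 0 & bc$color_value <= 1))

  # with unit sds the back-scaled values are the raw coefficients
  sc_unit <- sc
  sc_unit$scale[] <- 1
  m_unit <- m
  m_unit$scaler <- sc_unit
  expect_equal(backscaled_coefficients(m_unit)$back_coef,
               unname(m$coefficients), tolerance = 1e-12)
})

test_that("back-scaled coefficient signs track the group mean difference", {
  # strong noise-free planted contrast: bins with |t| > 2 must agree
  coh <- simulate_cohort(quick_config(fold_changes = c(A = 0.8, B = 1.4),
                                      noise_sd = 0.05,
                                      n_treated = 8, n_control = 8))
  tab <- normalize_constant_sum(build_bucket_table(coh$spectra,
                                                   quick_grid()))
  st <- student_t_per_bin(tab)
  m <- fit_oplsda(uv_scale(tab), tab$groups, n_orth = 1, cv_folds = 0)
  bc <- backscaled_coefficients(m)
  idx <- match(sprintf("%.3f", bc$ppm), sprintf("%.3f", st$bin_ppm))
  strong <- which(abs(st$t_stat[idx]) > 2)
  # treated coded 1, control 2: an elevated bin predicts a LOWER score,
  # so the coefficient sign is opposite to the mean difference
  diffs <- (st$mean_treated - st$mean_control)[idx]
  expect_true(all(sign(bc$back_coef[strong]) == -sign(diffs[strong])))
})

test_that("prediction honours the training scaler contract", {
  d <- random_labelled_matrix(77, n = 12, p = 8, effect = 1)
  X <- d$X
  X[, 8] <- 3  # constant column dropped at scaling
  sc <- uv_scale(X)
  m <- fit_oplsda(sc, d$groups, n_orth = 1, cv_folds = 0)
  new_full <- X[1:4, , drop = FALSE]
  new_wo <- new_full[, 1:7]
  expect_equal(predict(m, new_full), predict(m, new_wo))
  expect_error(predict(m, new_full[, 1:3]), "lacks")
})

test_that("internal Q2 equals a brute-force refit-per-fold hold-out loop", {
  for (s in c(2, 9)) {
    d <- random_labelled_matrix(s, n = 15, p = 10, effect = 1.5)
    m <- fit_oplsda(uv_scale(d$X), d$groups, n_orth = 1, cv_folds = 5,
                    seed = s)
    y <- ifelse(d$groups == "treated", 1, 2)
    expect_equal(m$q2, brute_force_q2(d$X, y, 1, 5, s), tolerance = 1e-10)
    expect_lte(m$q2, m$r2y + 1e-9)
  }
})
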