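make_table <- function(values, groups) {
  colnames(values) <- sprintf("%.3f", seq_len(ncol(values)))
  structure(list(sample_ids = paste0("s", seq_len(nrow(values))),
                 groups = groups, bin_centers = seq_len(ncol(values)),
                 values = values, normalized = TRUE, grid = NULL),
            class = "bucket_table")
}

test_that("pooled t-statistics match the closed form and stats::t.test", {
  tab <- make_table(cbind(c(1, 2, 3, 2, 3, 4)),
                    rep(c("treated", "control"), each = 3))
  st <- student_t_per_bin(tab)
  expect_equal(st$t_stat, -1.2247, tolerance = 1e-4)
  expect_equal(st$p_value, 0.2879, tolerance = 1e-3)
  tt <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(st$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(st$fold_change, 2 / 3, tolerance = 1e-12)
  expect_equal(st$direction, "down")

  # vectorised path agrees with t.test on random data, every bin
  set.seed(3)
  vals <- matrix(abs(rnorm(9 * 8, 5)), 9, 8)
  vals <- vals / rowSums(vals)
  g <- rep(c("treated", "control"), c(5, 4))
  st2 <- student_t_per_bin(make_table(vals, g))
  for (j in 1:8) {
    tt <- t.test(vals[g == "treated", j], vals[g == "control", j],
                 var.equal = TRUE)
    expect_equal(st2$t_stat[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(st2$p_value[j], tt$p.value, tolerance = 1e-12)
  }
})

test_that("t-test antisymmetry and degenerate-variance handling", {
  set.seed(4)
  vals <- matrix(abs(rnorm(10 * 6, 5)), 10, 6)
  g <- rep(c("treated", "control"), each = 5)
  a <- student_t_per_bin(make_table(vals, g))
  b <- student_t_per_bin(make_table(vals, g), treated = "control",
                         control = "treated")
  expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  vals_id <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  same <- student_t_per_bin(make_table(vals_id,
                                       rep(c("treated", "control"),
                                           each = 3)))
  expect_true(all(same$t_stat == 0) && all(same$p_value == 1))

  # zero variance, unequal means: degenerate flag, p = 0
  vals_dg <- cbind(rep(c(1, 2), each = 3))
  dg <- student_t_per_bin(make_table(vals_dg, rep(c("treated", "control"),
                                                  each = 3)))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)

  expect_error(student_t_per_bin(make_table(vals[1:3, ],
                                            c("treated", "control",
                                              "control"))),
               "at least 2")
})

test_that("fixed-lambda Storey q-values reproduce the hand-computed step-up example", {
  p <- c(0.01, 0.02, 0.8, 0.9)
  qr <- storey_qvalues(p, method = "fixed", lambda = 0.5)
  expect_equal(qr$pi0, 1)
  expect_equal(qr$qvalues, c(0.04, 0.04, 0.9, 0.9), tolerance = 1e-12)
  expect_equal(qr$qvalues, stepup_qvalues(p, qr$pi0), tolerance = 1e-15)

  expect_equal(storey_qvalues(rep(1, 5), "fixed", 0.5)$qvalues, rep(1, 5))
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p, capped at 1, and reduce to BH when pi0 = 1", {
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(40)^(1 + rep / 2)
    qr <- storey_qvalues(p, method = "fixed", lambda = 0.5)
    ord <- order(p)
    expect_true(all(diff(qr$qvalues[ord]) >= -1e-12))
    expect_true(all(qr$qvalues <= 1 & qr$qvalues >= 0))
    expect_equal(qr$qvalues, stepup_qvalues(p, qr$pi0), tolerance = 1e-12)
    # with pi0 forced to 1 the step-up minima are exactly BH
    q1 <- stepup_qvalues(p, 1)
    expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("smoother pi0 is consistent on uniform p-values", {
  set.seed(21)
  p <- runif(5000)
  qr <- storey_qvalues(p, method = "smoother")
  expect_lt(abs(qr$pi0 - 1), 0.05)
  expect_equal(qr$method, "smoother")
  expect_equal(qr$lambda_grid, seq(0.05, 0.95, by = 0.05))
})

test_that("type-I error of the per-bin test is calibrated on null cohorts", {
  # no planted effect: the fraction of bins with p < 0.05 stays near 0.05
  n_lt <- 0; n_tot <- 0
  for (r in 1:30) {
    coh <- simulate_cohort(quick_config(seed = 900 + r,
                                        fold_changes = numeric(0),
                                        noise_sd = 0.5,
                                        n_treated = 6, n_control = 6))
    tab <- normalize_constant_sum(build_bucket_table(coh$spectra,
                                                     quick_grid()))
    st <- student_t_per_bin(tab)
    n_lt <- n_lt + sum(st$p_value < 0.05)
    n_tot <- n_tot + nrow(st)
  }
  frac <- n_lt / n_tot
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})
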