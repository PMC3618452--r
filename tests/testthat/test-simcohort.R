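test_that("rendered spectra peak at the template shift and are linear in amplitude", {
  grid <- c(1, 2, 5e-4)
  sp <- render_spectrum(single_template(1.325), c(GABA = 1), grid)
  expect_equal(sp$ppm[which.max(sp$intensity)], 1.325, tolerance = 5e-4)
  expect_true(all(is.finite(sp$intensity)) && all(sp$intensity >= 0))

  empty <- render_spectrum(single_template()[0, ], numeric(0), grid)
  expect_true(all(empty$intensity == 0))

  tpl <- tiny_templates()
  one <- render_spectrum(tpl, c(A = 2, B = 1), c(0.5, 7.5, 1e-3))
  two <- render_spectrum(tpl, c(A = 4, B = 2), c(0.5, 7.5, 1e-3))
  expect_equal(two$intensity, 2 * one$intensity)

  expect_error(render_spectrum(tpl, c(A = 1, Z = 1), grid),
               "unknown metabolite")
})

test_that("cohort simulation is seed-deterministic and honours the null model", {
  cfg <- quick_config(seed = 42, noise_sd = 0.3)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(quick_config(seed = 42, noise_sd = 0.3))
  expect_identical(lapply(c1$spectra, `[[`, "intensity"),
                   lapply(c2$spectra, `[[`, "intensity"))
  c3 <- simulate_cohort(quick_config(seed = 43, noise_sd = 0.3))
  expect_false(identical(c1$spectra[[1]]$intensity,
                         c3$spectra[[1]]$intensity))

  # no noise, no effect: every treated spectrum equals every control one
  null0 <- simulate_cohort(quick_config(fold_changes = numeric(0)))
  ints <- lapply(null0$spectra, `[[`, "intensity")
  expect_true(all(vapply(ints, identical, logical(1), ints[[1]])))
  expect_length(null0$truth$affected, 0)
  expect_true(all(null0$truth$fold_changes == 1))
})

test_that("group sizes, labels and ground truth reflect the configuration", {
  coh <- simulate_cohort(quick_config())
  expect_length(coh$spectra, 9)
  expect_equal(sum(coh$manifest$group == "treated"), 5)
  expect_equal(sum(coh$manifest$group == "control"), 4)
  expect_equal(coh$truth$affected, "B")
  expect_equal(unname(coh$truth$fold_changes["B"]), 1.5)

  cfg_default <- sim_config()
  expect_equal(cfg_default$n_treated, 12L)
  expect_equal(cfg_default$n_control, 11L)

  expect_error(sim_config(n_treated = 1), "at least 2")
  expect_error(quick_config(fold_changes = c(B = -1)), "positive")
  expect_error(sim_config(grid = c(5, 1, 0.001)), "min < max")
})

test_that("planted multiplicative effects are exact at zero noise (isolated peak)", {
  # single metabolite: no tail cross-contamination, ratio is exact
  cfg <- sim_config(n_treated = 3, n_control = 3,
                    templates = single_template(1.325),
                    fold_changes = c(GABA = 1.5),
                    base_amplitudes = c(GABA = 1),
                    noise_sd = 0, grid = c(1, 2, 5e-4), seed = 1)
  coh <- simulate_cohort(cfg)
  grid <- bucket_grid(range = c(1, 2), exclusions = list())
  tab <- build_bucket_table(coh$spectra, grid)
  tr <- colMeans(tab$values[tab$groups == "treated", ])
  ct <- colMeans(tab$values[tab$groups == "control", ])
  expect_true(all(abs(tr / ct - 1.5) <= 1e-10))
})

test_that("planted bucket ratios match fold changes up to Lorentzian tail leakage", {
  coh <- simulate_cohort(quick_config(fold_changes = c(B = 1.5)))
  tab <- build_bucket_table(coh$spectra, quick_grid())
  tr <- colMeans(tab$values[tab$groups == "treated", ])
  ct <- colMeans(tab$values[tab$groups == "control", ])
  ratio <- tr / ct
  b_bins <- abs(tab$bin_centers - 7.1) < 0.02
  a_bins <- abs(tab$bin_centers - 0.95) < 0.1
  expect_true(all(abs(ratio[b_bins] - 1.5) < 1e-2))
  expect_true(all(abs(ratio[a_bins] - 1.0) < 1e-2))
})

test_that("written cohorts round-trip through the spectrum reader", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(quick_config(noise_sd = 0.2))
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, length(coh$spectra))
  expect_equal(back[[1]]$group, coh$spectra[[1]]$group)
  expect_equal(back[[3]]$intensity, coh$spectra[[3]]$intensity,
               tolerance = 1e-12)
  gt <- read.table(file.path(dir, "ground_truth.tsv"), header = TRUE,
                   sep = "\t")
  expect_true(all(gt$affected == (gt$metabolite %in% coh$truth$affected)))
})

test_that("noise calibration hits the requested per-bin SNR at the median bin", {
  cfg <- sim_config(seed = 1)
  ns <- noise_sd_for_bin_snr(cfg, snr = 3)
  expect_gt(ns, 0)
  # reconstruct: median affected-bin delta / (bucket noise sd) == 3
  grid <- bucket_grid()
  lib <- default_shift_library()
  mets <- unique(cfg$templates$metabolite)
  fc <- setNames(rep(1, length(mets)), mets)
  fc[names(cfg$fold_changes)] <- cfg$fold_changes
  amp <- cfg$base_amplitudes[mets]
  st <- render_spectrum(cfg$templates, amp * fc[mets], cfg$grid)
  sc <- render_spectrum(cfg$templates, amp, cfg$grid)
  bt <- bin_spectrum(make_spectrum("t", st$ppm, st$intensity), grid)
  bc <- bin_spectrum(make_spectrum("c", sc$ppm, sc$intensity), grid)
  lib_aff <- lib[lib$metabolite %in% names(fc)[fc != 1], ]
  in_lib <- sapply(bt$bin_centers,
                   function(p) any(p >= lib_aff$lo_ppm & p < lib_aff$hi_ppm))
  delta <- abs(bt$bin_values - bc$bin_values)[in_lib]
  delta <- delta[delta > 0]
  snr <- median(delta) / (ns * sqrt(grid$width / cfg$grid[3]))
  expect_equal(snr, 3, tolerance = 1e-9)
})
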