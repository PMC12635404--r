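test_that("noiseless self-fit recovers the generating parameters", {
  truth <- kinetic_params(5.278e-5, 9, 17, "apparent", S0 = 1)
  series <- evolve_closed_form(truth, times = seq(0, 179))
  fit <- fit_two_pool(series)
  expect_true(fit$converged)
  expect_equal(fit$params_hat$k_per_s, truth$k_per_s, tolerance = 1e-6)
  expect_equal(fit$params_hat$T1_substrate_s, 9, tolerance = 1e-6)
  expect_equal(fit$params_hat$T1_product_s, 17, tolerance = 1e-6)
  expect_equal(fit$params_hat$S0, 1, tolerance = 1e-6)
  expect_gt(fit$r2_substrate, 1 - 1e-10)
  expect_gt(fit$r2_product, 1 - 1e-10)
})

test_that("a zero product trace drives k to its lower bound and still recovers substrate T1", {
  truth <- kinetic_params(0, 30, 16, "apparent", S0 = 1)
  series <- evolve_closed_form(truth, times = seq(0, 238, by = 2))
  fit <- fit_two_pool(series)
  expect_lt(fit$params_hat$k_per_s, 1e-9)
  expect_equal(fit$params_hat$T1_substrate_s, 30, tolerance = 1e-4)
  expect_true(is.na(fit$r2_product))
})

test_that("fit is invariant to a common positive rescaling of both traces", {
  sc <- hp_preset("day7", seed = 5)
  series <- generate_dynamic(sc)
  f1 <- fit_two_pool(series)
  scaled <- dynamic_series(series$times_s, 250 * series$substrate_signal,
                           250 * series$product_signal)
  f2 <- fit_two_pool(scaled)
  # identical up to optimizer convergence tolerance
  expect_equal(f2$params_hat$k_per_s, f1$params_hat$k_per_s,
               tolerance = 1e-3)
  expect_equal(f2$params_hat$T1_substrate_s, f1$params_hat$T1_substrate_s,
               tolerance = 1e-3)
  expect_equal(f2$params_hat$T1_product_s, f1$params_hat$T1_product_s,
               tolerance = 1e-3)
  expect_equal(f2$params_hat$S0, 250 * f1$params_hat$S0, tolerance = 1e-3)
})

test_that("flat traces are rejected as below detection; short series rejected", {
  flat <- dynamic_series(0:9, rep(0, 10), rep(0, 10))
  expect_error(fit_two_pool(flat), "below detection")
  short <- quick_series(n = 5)
  expect_error(fit_two_pool(short), "at least 8")
})

test_that("parameter recovery holds across the physiological parameter range", {
  n_sets <- 150
  draws <- withr::with_seed(20, data.frame(
    k = exp(stats::runif(n_sets, log(1e-5), log(1.5e-4))),
    T1s = stats::runif(n_sets, 8, 40),
    T1p = stats::runif(n_sets, 8, 40),
    noise = stats::runif(n_sets, 0.005, 0.02)))
  ratio <- vapply(seq_len(n_sets), function(i) {
    sc <- ddnp_scenario(
      truth = kinetic_params(draws$k[i], draws$T1s[i], draws$T1p[i],
                             "apparent", S0 = 1),
      acq = acquisition_params(15, 1, 180),
      noise_sd_frac = draws$noise[i], seed = 1000 + i)
    fit_two_pool(generate_dynamic(sc))$params_hat$k_per_s / draws$k[i]
  }, numeric(1))
  expect_lte(stats::median(abs(ratio - 1)), 0.10)
  expect_lte(abs(stats::median(ratio) - 1), 0.03)
})

test_that("r_squared matches its definition and guards degeneracy", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9, 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("fold_change is a plain ratio with reciprocal symmetry", {
  # day-7 over day-14 rate constants: the reported 4.6-fold decrease
  expect_equal(fold_change(5.278e-5, 1.146e-5), 4.605, tolerance = 1e-3)
  expect_equal(fold_change(3.2, 3.2), 1)
  expect_equal(fold_change(0, 5), 0)
  expect_error(fold_change(1, 0), "denominator")
  withr::with_seed(3, {
    a <- stats::runif(20, 0.1, 10); b <- stats::runif(20, 0.1, 10)
    expect_equal(fold_change(a, b) * fold_change(b, a), rep(1, 20))
  })
})

test_that("paired t-test matches hand arithmetic and handles degenerate differences", {
  id <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  # differences 1.1, 1.0, 0.9: mean 1, sd 0.1, t = 1/(0.1/sqrt(3))
  b <- c(5, 7, 2)
  res <- paired_t_test(b + c(1.1, 1.0, 0.9), b)
  expect_equal(res$t, sqrt(3) / 0.1, tolerance = 1e-10)
  expect_equal(res$p, 2 * stats::pt(-sqrt(3) / 0.1, df = 2),
               tolerance = 1e-10)
  # antisymmetry
  swap <- paired_t_test(b, b + c(1.1, 1.0, 0.9))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
  # constant non-zero differences
  expect_warning(inf <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "infinite")
  expect_identical(inf$t, Inf)
  expect_equal(inf$p, 0)
})

test_that("summed-spectra quantification is linear and flags detectability correctly", {
  sc <- hp_preset("day7", seed = 9)
  sc$render_spectra <- TRUE
  sp <- attr(generate_dynamic(sc), "spectra")
  q50 <- summed_quantification(sp, 50, sc$peaks)
  # linearity: integral of summed spectrum = sum of per-scan integrals
  per_scan <- vapply(1:50, function(i)
    integrate_peak(sp$intensities[i, ], sp$ppm_axis,
                   sc$peaks$product$window_ppm), numeric(1))
  expect_equal(q50$integral[q50$name == "lactate"], sum(per_scan),
               tolerance = 1e-10)
  # n_first = 1 equals single-spectrum integration
  q1 <- summed_quantification(sp, 1, sc$peaks)
  expect_equal(q1$integral[q1$name == "glucose"],
               integrate_peak(sp$intensities[1, ], sp$ppm_axis,
                              sc$peaks$substrate$window_ppm),
               tolerance = 1e-10)
  # detectable product on a day-7-like run...
  expect_true(all(q50$detectable))
  # ...but not when the product amplitude is zero (day-1-like)
  sc0 <- hp_preset("day7", seed = 10)
  sc0$render_spectra <- TRUE
  sc0$truth <- kinetic_params(0, 9, 17, "apparent", S0 = 1)
  q0 <- summed_quantification(attr(generate_dynamic(sc0), "spectra"), 50,
                              sc0$peaks)
  expect_true(q0$detectable[q0$name == "glucose"])
  expect_false(q0$detectable[q0$name == "lactate"])
  expect_error(summed_quantification(sp, 10 * nrow(sp$intensities),
                                     sc$peaks), "n_first")
})
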