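test_that("closed form matches numerical ODE integration", {
  tt <- seq(0, 240, by = 2)
  # reference conditions
  cf <- evolve_closed_form(fig1a_truth(), times = tt)
  od <- evolve_ode(fig1a_truth(), times = tt, rel_tol = 1e-12)
  expect_lt(max(abs(cf$substrate_signal - od$substrate_signal)) /
              max(cf$substrate_signal), 1e-8)
  expect_lt(max(abs(cf$product_signal - od$product_signal)) /
              max(cf$product_signal), 1e-8)
  # randomized parameter grid
  withr::with_seed(42, {
    for (i in 1:20) {
      kp <- kinetic_params(stats::runif(1, 0, 1e-3),
                           stats::runif(1, 5, 60), stats::runif(1, 5, 60),
                           "apparent", S0 = stats::runif(1, 0.5, 2),
                           P0 = stats::runif(1, 0, 0.1))
      cf <- evolve_closed_form(kp, times = tt)
      od <- evolve_ode(kp, times = tt, rel_tol = 1e-12)
      expect_lt(max_dev_unit_peak(cf$substrate_signal, od$substrate_signal) +
                  max(abs(cf$product_signal - od$product_signal)) /
                    max(cf$product_signal, 1e-12), 2e-8)
    }
  })
})

test_that("no conversion means no product; degenerate a = b branch is the L'Hopital limit", {
  tt <- seq(0, 100, by = 1)
  none <- evolve_closed_form(kinetic_params(0, 30, 16, "apparent"), times = tt)
  expect_equal(none$product_signal, rep(0, length(tt)))
  # arrange a == b: k + 1/T1s = 1/T1p
  k <- 1e-3; T1s <- 30; T1p <- 1 / (k + 1 / T1s)
  deg <- evolve_closed_form(kinetic_params(k, T1s, T1p, "apparent"),
                            times = tt)
  a <- k + 1 / T1s
  expect_equal(deg$product_signal, k * tt * exp(-a * tt), tolerance = 1e-12)
  # and it is continuous: a nearby non-degenerate T1p gives nearly the same trace
  near <- evolve_closed_form(kinetic_params(k, T1s, T1p * (1 + 1e-7),
                                            "apparent"), times = tt)
  expect_lt(max(abs(near$product_signal - deg$product_signal)), 1e-8)
})

test_that("ODE handles trivial inputs: single time point and equal-T1 symmetry", {
  kp <- kinetic_params(0, 20, 20, "apparent", S0 = 2, P0 = 1)
  one <- evolve_ode(kp, times = 0)
  expect_equal(one$substrate_signal, 2)
  expect_equal(one$product_signal, 1)
  tt <- seq(0, 60, by = 3)
  both <- evolve_ode(kp, times = tt, rel_tol = 1e-12)
  expect_equal(both$substrate_signal / 2, both$product_signal / 1,
               tolerance = 1e-9)
})

test_that("input validation rejects bad times and parameters", {
  expect_error(evolve_closed_form(fig1a_truth(), times = c(0, 2, 2)),
               "strictly increasing")
  expect_error(kinetic_params(-1e-5, 30, 16), "k_per_s")
  expect_error(kinetic_params(1e-5, -30, 16), "T1")
  expect_error(acquisition_params(95, 1, 10), "flip_angle_deg")
  expect_error(acquisition_params(10, 0, 10), "repetition_time_s")
  expect_error(
    evolve_closed_form(kinetic_params(1e-5, 30, 16, "true"), times = 0:10),
    "acquisition_params required")
})

test_that("discrete-pulse simulator: zero flip angle records nothing and leaves magnetization on the closed-form path", {
  tp <- kinetic_params(5e-5, 38, 17, "true", S0 = 1)
  acq <- acquisition_params(0, 1, 60)
  dp <- simulate_discrete_pulses(tp, acq)
  expect_equal(dp$substrate_signal, rep(0, 60))
  expect_equal(dp$product_signal, rep(0, 60))
  long <- attr(dp, "longitudinal")
  cf <- evolve_closed_form(kinetic_params(5e-5, 38, 17, "apparent"),
                           times = long$time_s)
  expect_equal(long$S, cf$substrate_signal, tolerance = 1e-10)
  expect_equal(long$P, cf$product_signal, tolerance = 1e-10)
})

test_that("pure RF depletion is geometric in cos(pw)", {
  tp <- kinetic_params(0, 1e15, 1e15, "true", S0 = 1)
  acq <- acquisition_params(12, 1, 40)
  dp <- simulate_discrete_pulses(tp, acq)
  ratios <- dp$substrate_signal[-1] / dp$substrate_signal[-40]
  expect_equal(ratios, rep(cos(12 * pi / 180), 39), tolerance = 1e-9)
})

test_that("discrete recursion matches the continuous apparent-T1 approximation", {
  # reference case: true T1 38 s, pw 8 deg, TR 1 s, no conversion
  acq <- acquisition_params(8, 1, 120)
  tp <- kinetic_params(0, 38, 17, "true", S0 = 1)
  dp <- simulate_discrete_pulses(tp, acq)
  T1app <- apparent_from_true_T1(38, acq)
  expect_equal(T1app, 28, tolerance = 0.01)
  mono <- exp(-dp$times_s / T1app)
  expect_lt(max_dev_unit_peak(dp$substrate_signal, mono), 0.01)
  # with the exact -ln(cos pw)/TR folding the continuous apparent model
  # reproduces the discrete recursion identically, at any angle
  withr::with_seed(7, {
    for (i in 1:10) {
      pw <- stats::runif(1, 2, 25); TR <- stats::runif(1, 0.5, 2)
      T1s <- stats::runif(1, 9, 60); T1p <- stats::runif(1, 9, 60)
      k <- stats::runif(1, 1e-5, 2e-4)
      acq <- acquisition_params(pw, TR, 120)
      dp <- simulate_discrete_pulses(kinetic_params(k, T1s, T1p, "true"),
                                     acq)
      exact <- evolve_closed_form(
        kinetic_params(k, apparent_from_true_T1(T1s, acq, exact = TRUE),
                       apparent_from_true_T1(T1p, acq, exact = TRUE),
                       "apparent"),
        times = dp$times_s)
      expect_lt(max_dev_unit_peak(dp$substrate_signal,
                                  exact$substrate_signal), 1e-10)
      expect_lt(max_dev_unit_peak(dp$product_signal,
                                  exact$product_signal), 1e-10)
      # the conventional (1 - cos pw)/TR folding agrees within 1% at the
      # effective angles actually used (<= 15 degrees)
      if (pw <= 15) {
        app <- evolve_closed_form(
          kinetic_params(k, apparent_from_true_T1(T1s, acq),
                         apparent_from_true_T1(T1p, acq), "apparent"),
          times = dp$times_s)
        expect_lt(max_dev_unit_peak(dp$substrate_signal,
                                    app$substrate_signal), 0.01)
        expect_lt(max_dev_unit_peak(dp$product_signal,
                                    app$product_signal), 0.01)
      }
    }
  })
})

test_that("magnetization is conserved without pulsing and relaxation", {
  tp <- kinetic_params(2e-4, 1e15, 1e15, "true", S0 = 1)
  dp <- simulate_discrete_pulses(tp, acquisition_params(0, 2, 120))
  long <- attr(dp, "longitudinal")
  expect_equal(long$S + long$P, rep(1, 120), tolerance = 1e-9)
})

test_that("peak product signal is non-decreasing in k", {
  tt <- seq(0, 240, by = 2)
  peaks <- vapply(c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3), function(k) {
    max(evolve_closed_form(kinetic_params(k, 30, 16, "apparent"),
                           times = tt)$product_signal)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("flip-angle T1 conversions reproduce the reported corrections and invert exactly", {
  acq8 <- acquisition_params(8, 1, 100)
  acq15 <- acquisition_params(15, 1, 100)
  # pyruvate run: apparent 28 s -> true 38.5 s (reported as 38)
  expect_equal(correct_T1_apparent(28, acq8), 38.488, tolerance = 1e-4)
  # glucose-run lactate: apparent 17 s -> true 40.4 s (reported as 41)
  expect_equal(correct_T1_apparent(17, acq15), 40.405, tolerance = 1e-4)
  # identity at pw = 0
  acq0 <- acquisition_params(0, 1, 100)
  expect_equal(correct_T1_apparent(23.4, acq0), 23.4, tolerance = 1e-15)
  expect_equal(apparent_from_true_T1(23.4, acq0), 23.4, tolerance = 1e-15)
  # round trips to machine precision over a grid
  withr::with_seed(11, {
    T1 <- stats::runif(50, 2, 100)
    pw <- stats::runif(50, 0, 25)
    TR <- stats::runif(50, 0.5, 3)
    for (i in 1:50) {
      acq <- acquisition_params(pw[i], TR[i], 10)
      expect_equal(correct_T1_apparent(apparent_from_true_T1(T1[i], acq),
                                       acq), T1[i], tolerance = 1e-12)
      app <- apparent_from_true_T1(T1[i], acq)
      expect_equal(apparent_from_true_T1(correct_T1_apparent(app, acq), acq),
                   app, tolerance = 1e-12)
    }
  })
  # correction rejects apparent decay slower than the pulsing rate alone
  fast <- acquisition_params(25, 0.5, 100)
  expect_error(correct_T1_apparent(60, fast), "pulsing rate")
})
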