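test_that("default carbon-13 peak table is well-formed and disjoint", {
  pks <- default_c13_peaks()
  expect_named(pks, c("pyruvate_c2", "lactate", "pyruvate_hydrate",
                      "bicarbonate", "glucose"))
  expect_equal(pks$lactate$J_Hz, 55)
  expect_equal(pks$lactate$center_ppm, 183.5)
  windows <- t(vapply(pks, function(p) p$window_ppm, numeric(2)))
  windows <- windows[order(windows[, 1]), ]
  expect_true(all(windows[-1, 1] >= windows[-nrow(windows), 2]))
})

test_that("Hz/ppm conversions are exact inverses", {
  x <- c(0.5, 55, 123.4)
  expect_equal(ppm_to_hz(hz_to_ppm(x, 125.77), 125.77), x)
  expect_equal(hz_to_ppm(ppm_to_hz(x, 500), 500), x)
})

test_that("a noiseless singlet peaks at its center with integral proportional to amplitude", {
  axis <- c13_axis(step = 0.005)
  for (A in c(1, 3.7)) {
    pk <- peak_definition("x", 150, c(145, 155), linewidth_Hz = 4,
                          amplitude = A)
    y <- synthesize_spectrum(pk, axis, 125.77)
    expect_equal(max(y), A, tolerance = 1e-3)
    expect_equal(axis[which.max(y)], 150, tolerance = 0.005)
    # Lorentzian area = A * pi * hwhm
    hw <- (4 / 125.77) / 2
    expect_equal(integrate_peak(y, axis, c(145, 155)), A * pi * hw,
                 tolerance = 0.02)
  }
})

test_that("a J = 55 Hz doublet splits into half-amplitude components 0.437 ppm apart", {
  axis <- c13_axis(step = 0.01)
  y <- synthesize_spectrum(lactate_doublet(), axis, 125.77)
  # local maxima
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  locmax <- locmax[y[locmax] > 0.1]
  expect_length(locmax, 2)
  sep_ppm <- abs(diff(axis[locmax]))
  expect_equal(sep_ppm, 55 / 125.77, tolerance = 0.03)
  expect_equal(y[locmax] / max(y), c(1, 1), tolerance = 0.02)
})

test_that("spectrum synthesis and window integration are linear", {
  axis <- c13_axis(step = 0.01)
  p1 <- peak_definition("a", 120, c(117, 123), linewidth_Hz = 3,
                        amplitude = 2)
  p2 <- peak_definition("b", 170, c(167, 173), linewidth_Hz = 5,
                        amplitude = 0.5)
  y1 <- synthesize_spectrum(p1, axis, 125.77)
  y2 <- synthesize_spectrum(p2, axis, 125.77)
  y12 <- synthesize_spectrum(list(p1, p2), axis, 125.77)
  expect_equal(y12, y1 + y2, tolerance = 1e-12)
  w <- c(115, 125)
  expect_equal(integrate_peak(3 * y1 + 2 * y2, axis, w),
               3 * integrate_peak(y1, axis, w) +
                 2 * integrate_peak(y2, axis, w), tolerance = 1e-12)
})

test_that("integration handles trivial shapes and splitting conserves area", {
  axis <- seq(10, 0, by = -0.01)
  expect_equal(integrate_peak(numeric(length(axis)), axis, c(2, 8)), 0)
  rect <- as.numeric(axis >= 4 & axis < 6)   # height 1, width 2
  expect_equal(integrate_peak(rect, axis, c(3, 7)), 2, tolerance = 0.011)
  # doublet vs equal-area singlet over a wide window
  axis13 <- c13_axis(step = 0.002)
  wide <- c(178, 189)
  d <- synthesize_spectrum(
    peak_definition("d", 183.5, wide, "doublet", J_Hz = 55,
                    linewidth_Hz = 2), axis13, 125.77)
  s <- synthesize_spectrum(
    peak_definition("s", 183.5, wide, linewidth_Hz = 2), axis13, 125.77)
  expect_equal(integrate_peak(d, axis13, wide),
               integrate_peak(s, axis13, wide), tolerance = 0.01)
  expect_error(integrate_peak(s, axis13, c(300, 310)), "outside")
})

test_that("reducing a rendered series recovers the generating traces", {
  sc <- hp_preset("day7", seed = 2)
  sc$render_spectra <- TRUE
  sc$noise_sd_frac <- 0
  sc$spectral_noise_frac <- 0
  ds <- generate_dynamic(sc)
  sp <- attr(ds, "spectra")
  red <- series_to_dynamic(sp, sc$peaks$substrate, sc$peaks$product)
  expect_gte(stats::cor(red$substrate_signal, ds$substrate_signal), 0.999)
  expect_gte(stats::cor(red$product_signal, ds$product_signal), 0.999)
  expect_equal(red$times_s, ds$times_s)
  # scrambling scan order scrambles outputs identically (no smoothing)
  perm <- withr::with_seed(1, sample(nrow(sp$intensities)))
  sp_perm <- spectrum_series(sp$ppm_axis, sp$intensities[perm, ],
                             sp$freq_MHz, sort(sp$scan_times_s))
  red_perm <- series_to_dynamic(sp_perm, sc$peaks$substrate,
                                sc$peaks$product)
  expect_equal(red_perm$substrate_signal, red$substrate_signal[perm])
  # single-scan series reduces to a one-row trace
  sp1 <- spectrum_series(sp$ppm_axis, sp$intensities[1, , drop = FALSE],
                         sp$freq_MHz, sp$scan_times_s[1])
  expect_equal(length(series_to_dynamic(sp1, sc$peaks$substrate,
                                        sc$peaks$product)), 1L)
  # overlapping windows are flagged
  ov <- peak_definition("ov", 95.5, c(94, 99), linewidth_Hz = 5)
  expect_warning(series_to_dynamic(sp1, sc$peaks$substrate, ov), "overlap")
})

test_that("noise estimation is robust, offset-invariant and rejects peak overlap", {
  axis <- c13_axis(step = 0.01)
  win <- c(100, 102)   # 200 points
  withr::with_seed(5, {
    errs <- vapply(1:20, function(i) {
      y <- stats::rnorm(length(axis), sd = 0.37)
      estimate_noise(y, axis, win) / 0.37 - 1
    }, numeric(1))
    expect_lt(stats::median(abs(errs)), 0.15)
  })
  y <- withr::with_seed(6, stats::rnorm(length(axis), sd = 1))
  expect_equal(estimate_noise(y + 100, axis, win),
               estimate_noise(y, axis, win), tolerance = 1e-10)
  expect_equal(estimate_noise(numeric(length(axis)), axis, win), 0)
  expect_error(estimate_noise(y, axis, c(100, 100.1)), "at least 16")
  pk <- peak_definition("p", 101, c(99, 103), linewidth_Hz = 3)
  expect_error(estimate_noise(y, axis, win, peaks = list(pk)), "overlaps")
})
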