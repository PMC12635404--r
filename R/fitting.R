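# Least-squares estimation of the apparent rate constant and apparent T1s.
#
# Fitting follows the low-SNR-robust convention: the pulse angle is set to
# zero in the model, so the fitted T1s are apparent values that fold in the
# pulsing losses; the flip-angle correction is applied afterwards with
# correct_T1_apparent().

#' Configuration of the two-pool fit
#'
#' @param k_bounds Length-2 bounds on k, 1/s. Default `c(0, 1e-2)`,
#'   generous and physics-motivated.
#' @param T1_bounds Length-2 bounds on both apparent T1s, seconds.
#' @param T1_substrate_init,T1_product_init Initial T1 guesses, seconds.
#' @param k_init Initial k guess, or `NULL` to derive it from the initial
#'   product slope divided by the substrate peak.
#' @param fit_P0 If `TRUE`, the product amplitude at t = 0 is a free
#'   parameter; by default it is fixed at 0 (no product at injection).
#' @param weighting `"uniform"` or `"inverse-variance"` (each trace's
#'   residuals scaled by the reciprocal of its sample SD, balancing the two
#'   pools' very different amplitudes).
#' @param n_starts Number of multistart initializations (first is the base
#'   guess, the rest are seeded log-normal perturbations of it).
#' @param random_seed Seed for the multistart perturbations.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(k_bounds = c(0, 1e-2), T1_bounds = c(1, 120),
                       T1_substrate_init = 30, T1_product_init = 20,
                       k_init = NULL, fit_P0 = FALSE,
                       weighting = c("uniform", "inverse-variance"),
                       n_starts = 5, random_seed = 101) {
  weighting <- match.arg(weighting)
  stopifnot(length(k_bounds) == 2L, k_bounds[1] < k_bounds[2],
            length(T1_bounds) == 2L, T1_bounds[1] < T1_bounds[2],
            T1_bounds[1] > 0, n_starts >= 1)
  if (T1_substrate_init < T1_bounds[1] || T1_substrate_init > T1_bounds[2] ||
      T1_product_init < T1_bounds[1] || T1_product_init > T1_bounds[2])
    stop("initial T1 guesses must lie within T1_bounds")
  if (!is.null(k_init) && (k_init < k_bounds[1] || k_init > k_bounds[2]))
    stop("k_init must lie within k_bounds")
  structure(
    list(k_bounds = k_bounds, T1_bounds = T1_bounds,
         T1_substrate_init = T1_substrate_init,
         T1_product_init = T1_product_init, k_init = k_init,
         fit_P0 = fit_P0, weighting = weighting,
         n_starts = as.integer(n_starts), random_seed = random_seed),
    class = "fit_config"
  )
}

# data-driven k guess: early product slope over substrate peak
.k_guess <- function(series, config) {
  t <- series$times_s; P <- series$product_signal
  speak <- max(series$substrate_signal)
  j <- max(3L, floor(which.max(P) / 2))
  j <- min(j, length(t))
  slope <- (P[j] - P[1]) / (t[j] - t[1])
  k0 <- slope / speak
  if (!is.finite(k0) || k0 <= config$k_bounds[1]) k0 <- 1e-5
  min(max(k0, config$k_bounds[1] + 1e-9), config$k_bounds[2])
}

#' Fit the two-pool model to a dynamic series
#'
#' Joint least squares of the substrate and product traces against the
#' closed-form two-pool solution with the pulsing rate set to zero, via
#' bounded Levenberg-Marquardt ([minpack.lm::nls.lm()]) with multistart.
#' Free parameters by default: `k`, the two apparent T1s and `S0`, with `P0`
#' fixed at 0. Standard errors come from the Jacobian-based covariance at
#' the optimum; per-trace goodness of fit from [r_squared()].
#'
#' @param series A [dynamic_series()] with at least 8 time points and a
#'   positive substrate peak.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params_hat`
#'   ([kinetic_params()], apparent mode), `se` (named standard errors),
#'   `r2_substrate`, `r2_product`, `residual_norm`, `converged`, `n_points`,
#'   and `fitted` (the model evaluated at the observed times).
#' @export
fit_two_pool <- function(series, config = fit_config()) {
  stopifnot(inherits(series, "dynamic_series"))
  n <- length(series$times_s)
  if (n < 8L) stop("need at least 8 time points, got ", n)
  S <- series$substrate_signal; P <- series$product_signal
  t <- series$times_s - series$times_s[1]
  speak <- max(S)
  if (speak <= 0 || stats::sd(S) == 0)
    stop("substrate trace is below detection (flat or non-positive)")
  w_s <- 1; w_p <- 1
  if (config$weighting == "inverse-variance") {
    w_s <- 1 / max(stats::sd(S), .Machine$double.eps)
    w_p <- 1 / max(stats::sd(P), speak * 1e-6)
  }
  lower <- c(k = config$k_bounds[1], T1s = config$T1_bounds[1],
             T1p = config$T1_bounds[1], S0 = 0)
  upper <- c(k = config$k_bounds[2], T1s = config$T1_bounds[2],
             T1p = config$T1_bounds[2], S0 = Inf)
  if (config$fit_P0) {
    lower <- c(lower, P0 = 0); upper <- c(upper, P0 = Inf)
  }
  model <- function(par) {
    p0 <- if (config$fit_P0) par[["P0"]] else 0
    kp <- kinetic_params(par[["k"]], par[["T1s"]], par[["T1p"]],
                         T1_mode = "apparent", S0 = par[["S0"]], P0 = p0)
    evolve_closed_form(kp, times = t)
  }
  resid_fn <- function(par) {
    m <- model(par)
    c(w_s * (S - m$substrate_signal), w_p * (P - m$product_signal))
  }
  base <- c(k = .k_guess(series, config), T1s = config$T1_substrate_init,
            T1p = config$T1_product_init, S0 = speak)
  if (!is.null(config$k_init)) base[["k"]] <- config$k_init
  if (config$fit_P0) base <- c(base, P0 = max(P[1], 0))
  starts <- list(base)
  if (config$n_starts > 1L) {
    jitters <- withr::with_seed(config$random_seed, {
      lapply(seq_len(config$n_starts - 1L), function(i)
        exp(stats::rnorm(length(base), sd = 0.6)))
    })
    for (j in jitters) {
      st <- pmin(pmax(base * j, lower + 1e-12),
                 ifelse(is.finite(upper), upper, base * j))
      starts <- c(starts, list(st))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all multistart fits failed")
  par <- best$par
  converged <- best$info %in% 1:3
  se <- rep(NA_real_, length(par)); names(se) <- names(par)
  cov <- tryCatch({
    s <- summary(best)
    s$coefficients[, "Std. Error"]
  }, error = function(e) NULL)
  if (!is.null(cov)) se[names(cov)] <- cov
  m <- model(par)
  r2s <- tryCatch(r_squared(S, m$substrate_signal), error = function(e) NA_real_)
  r2p <- tryCatch(r_squared(P, m$product_signal), error = function(e) NA_real_)
  params_hat <- kinetic_params(par[["k"]], par[["T1s"]], par[["T1p"]],
                               T1_mode = "apparent", S0 = par[["S0"]],
                               P0 = if (config$fit_P0) par[["P0"]] else 0)
  structure(
    list(params_hat = params_hat, se = se,
         r2_substrate = r2s, r2_product = r2p,
         residual_norm = sqrt(sum((S - m$substrate_signal)^2 +
                                    (P - m$product_signal)^2)),
         converged = converged, n_points = n,
         fitted = dynamic_series(series$times_s, m$substrate_signal,
                                 m$product_signal, labels = series$labels)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params_hat
  cat(sprintf(
    "<fit_result> k = %.4g /s, T1app(S) = %.3g s, T1app(P) = %.3g s\n  R2 = %.4g (S) / %.4g (P), converged: %s, n = %d\n",
    p$k_per_s, p$T1_substrate_s, p$T1_product_s,
    x$r2_substrate, x$r2_product, x$converged, x$n_points))
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,fitted Equal-length numeric vectors (`>= 2` points);
#'   `observed` must not be constant.
#' @return Unitless R-squared (`<= 1`; can be negative for fits worse than
#'   the mean).
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R-squared undefined: observed vector is constant")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Ratio of two rate constants (fold change)
#'
#' @param value_a Numerator (e.g. the earlier time point's rate).
#' @param value_b Denominator, `> 0`.
#' @return `value_a / value_b`.
#' @export
fold_change <- function(value_a, value_b) {
  if (any(value_b <= 0)) stop("fold_change denominator must be > 0")
  value_a / value_b
}

#' Paired two-tailed t-test
#'
#' Standard paired t on the within-pair differences, two-tailed p from the t
#' distribution with n - 1 degrees of freedom. Pairs with zero-variance
#' differences are handled explicitly: all-zero differences give t = 0,
#' p = 1; constant non-zero differences give an infinite t (with a warning)
#' and p = 0.
#'
#' @param group_a,group_b Equal-length numeric vectors (`>= 2`), paired by
#'   subject (donor).
#' @return List with `t`, `p`, `df` and `mean_diff`.
#' @export
paired_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) == length(group_b), length(group_a) >= 2)
  d <- group_a - group_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    warning("zero-variance differences with non-zero mean: t is infinite")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                mean_diff = mean(d)))
  }
  res <- stats::t.test(group_a, group_b, paired = TRUE,
                       alternative = "two.sided")
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mean_diff = unname(res$estimate))
}

#' Summed-spectra quantification for low-flux samples
#'
#' When per-scan SNR is too low for kinetic fitting, the first `n_first`
#' spectra of the dynamic series are summed element-wise and each peak's
#' window is integrated in the summed spectrum. An SNR estimate accompanies
#' each integral: the summed intensity at the expected multiplet component
#' positions (matched detection at known shifts, robust to empty windows)
#' over the robust noise SD of a signal-free region of the summed spectrum,
#' together with the SNR >= 3 detectability flag.
#'
#' @param spectra A [spectrum_series()].
#' @param n_first Number of leading spectra to sum (default 50).
#' @param peaks List of [peak_definition()] to quantify.
#' @param noise_window Length-2 ppm window free of signal for the noise
#'   estimate, or `NULL` to use the widest axis region clear of all peak
#'   windows.
#' @param snr_threshold Detectability threshold (default 3).
#' @param baseline Subtract a linear baseline anchored at the window edges
#'   before integrating (removes the tails of large neighbouring peaks,
#'   the role baseline correction plays before integration of measured
#'   spectra).
#' @return Data frame with one row per peak: `name`, `integral`, `snr`,
#'   `detectable`.
#' @export
summed_quantification <- function(spectra, n_first = 50, peaks,
                                  noise_window = NULL, snr_threshold = 3,
                                  baseline = FALSE) {
  stopifnot(inherits(spectra, "spectrum_series"))
  if (inherits(peaks, "peak_definition")) peaks <- list(peaks)
  nsc <- nrow(spectra$intensities)
  if (n_first < 1 || n_first > nsc)
    stop("n_first must be between 1 and the number of scans (", nsc, ")")
  summed <- colSums(spectra$intensities[seq_len(n_first), , drop = FALSE])
  axis <- spectra$ppm_axis
  if (is.null(noise_window))
    noise_window <- .free_region(axis, peaks)
  sigma <- estimate_noise(summed, axis, noise_window, peaks = peaks)
  rows <- lapply(peaks, function(pk) {
    centers <- .peak_components(pk, spectra$freq_MHz)$center
    at <- vapply(centers, function(cp) which.min(abs(axis - cp)), integer(1))
    snr <- if (sigma > 0) max(summed[at]) / sigma else Inf
    data.frame(name = pk$name,
               integral = integrate_peak(summed, axis, pk$window_ppm,
                                         baseline = baseline),
               snr = snr, detectable = snr >= snr_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# widest axis gap clear of every peak window, with a small guard margin
.free_region <- function(axis, peaks) {
  lo <- min(axis); hi <- max(axis)
  step <- stats::median(abs(diff(axis)))
  margin <- 20 * step
  occ <- do.call(rbind, lapply(peaks, function(pk)
    pk$window_ppm + c(-margin, margin)))
  occ <- occ[order(occ[, 1]), , drop = FALSE]
  gaps <- list(c(lo, occ[1, 1]))
  for (i in seq_len(nrow(occ) - 1))
    gaps <- c(gaps, list(c(occ[i, 2], occ[i + 1, 1])))
  gaps <- c(gaps, list(c(occ[nrow(occ), 2], hi)))
  widths <- vapply(gaps, function(g) max(0, g[2] - g[1]), numeric(1))
  best <- gaps[[which.max(widths)]]
  if (max(widths) <= 17 * step)
    stop("no signal-free region available for noise estimation")
  best
}
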