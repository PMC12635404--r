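# Two-pool forward models.
#
# The hyperpolarized substrate pool S converts unidirectionally into the
# product pool P while both relax and are depleted by RF sampling:
#
#   dS/dt = -k S - S/T1_s - p S
#   dP/dt =  k S - P/T1_p - p P
#
# with p = (1 - cos pw)/TR. When the T1 values are *apparent* the pulsing
# losses are already folded into them and p is set to 0.

# effective decay rates (a = substrate, b = product) for a parameter set
.decay_rates <- function(params, acq) {
  p <- if (params$T1_mode == "apparent") {
    0
  } else {
    if (is.null(acq))
      stop("acquisition_params required when T1_mode = 'true' (pulsing term)")
    pulsing_rate(acq)
  }
  list(a = params$k_per_s + 1 / params$T1_substrate_s + p,
       b = 1 / params$T1_product_s + p,
       p = p)
}

# threshold for the degenerate a == b closed-form branch, 1/s
.AB_DEGENERATE_TOL <- 1e-10

#' Closed-form solution of the two-pool model
#'
#' Analytic solution of the linear pair: with `a = k + 1/T1_s + p` and
#' `b = 1/T1_p + p`,
#' \deqn{S(t) = S_0 e^{-at}}
#' \deqn{P(t) = P_0 e^{-bt} + k S_0 \frac{e^{-at} - e^{-bt}}{b - a}}
#' falling back to the L'Hopital limit \eqn{k S_0 t e^{-at}} when
#' `|b - a| < 1e-10` per second. Time is measured from the first recorded
#' scan; amplitudes refer to t = 0.
#'
#' @param params A [kinetic_params()] object. If `T1_mode = "apparent"` the
#'   pulsing rate is 0 and `acq` may be `NULL`; if `"true"`, `p` is taken
#'   from `acq`.
#' @param acq An [acquisition_params()] object or `NULL`.
#' @param times Numeric vector of evaluation times, seconds, strictly
#'   increasing, `>= 0`.
#' @return A [dynamic_series()] with the model traces.
#' @export
evolve_closed_form <- function(params, acq = NULL, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be >= 0")
  r <- .decay_rates(params, acq)
  S <- params$S0 * exp(-r$a * times)
  P <- if (abs(r$b - r$a) < .AB_DEGENERATE_TOL) {
    params$P0 * exp(-r$b * times) +
      params$k_per_s * params$S0 * times * exp(-r$a * times)
  } else {
    params$P0 * exp(-r$b * times) +
      params$k_per_s * params$S0 *
        (exp(-r$a * times) - exp(-r$b * times)) / (r$b - r$a)
  }
  dynamic_series(times, S, P)
}

#' Numerical integration of the two-pool model
#'
#' Integrates the same ODE pair as [evolve_closed_form()] with `deSolve`'s
#' `lsoda`; used as an independent cross-check of the closed form and as the
#' evolution kernel of exploratory variants.
#'
#' @inheritParams evolve_closed_form
#' @param rel_tol Relative tolerance passed to the solver (default 1e-10).
#' @return A [dynamic_series()].
#' @export
evolve_ode <- function(params, acq = NULL, times, rel_tol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be >= 0")
  r <- .decay_rates(params, acq)
  if (length(times) == 1L)
    if (times[1] == 0)
      return(dynamic_series(times, params$S0, params$P0))
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  rhs <- function(t, y, parms) {
    list(c(S = -parms$a * y[["S"]],
           P = parms$k * y[["S"]] - parms$b * y[["P"]]))
  }
  scale <- max(params$S0, params$P0, 1)
  sol <- deSolve::ode(
    y = c(S = params$S0, P = params$P0), times = tt, func = rhs,
    parms = list(a = r$a, b = r$b, k = params$k_per_s),
    method = "lsoda", rtol = rel_tol, atol = rel_tol * scale
  )
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge; istate = ", attr(sol, "istate")[1],
         " (see deSolve::diagnostics)")
  if (prepend) sol <- sol[-1, , drop = FALSE]
  dynamic_series(times, sol[, "S"], sol[, "P"])
}

#' Discrete-pulse simulation of the recorded signal
#'
#' Oracle for the apparent-T1 approximation: between pulses the longitudinal
#' magnetizations evolve by the two-pool ODEs with `p = 0` and *true* T1s; at
#' each scan the recorded signal is the pre-pulse longitudinal value times
#' `sin(pw)`, after which both pools are multiplied by `cos(pw)`.
#'
#' @param true_params A [kinetic_params()] with `T1_mode = "true"`.
#' @param acq An [acquisition_params()]; scan i (i = 0..n-1) occurs at
#'   `t0_offset_s + i * TR`.
#' @return A [dynamic_series()] of recorded per-scan signals. The pre-pulse
#'   longitudinal magnetizations are attached as attribute `"longitudinal"`
#'   (a data frame with columns `time_s`, `S`, `P`).
#' @export
simulate_discrete_pulses <- function(true_params, acq) {
  stopifnot(inherits(true_params, "kinetic_params"),
            inherits(acq, "acquisition_params"))
  if (true_params$T1_mode != "true")
    stop("simulate_discrete_pulses requires T1_mode = 'true'")
  pw <- acq$flip_angle_deg * pi / 180
  cpw <- cos(pw); spw <- sin(pw)
  n <- acq$n_scans
  times <- acq$t0_offset_s + (seq_len(n) - 1) * acq$repetition_time_s
  # free evolution over one TR, p = 0
  step <- evolve_closed_form(
    kinetic_params(true_params$k_per_s, true_params$T1_substrate_s,
                   true_params$T1_product_s, T1_mode = "apparent",
                   S0 = 1, P0 = 0),
    times = c(0, acq$repetition_time_s))
  eS <- step$substrate_signal[2]          # substrate survival factor
  conv <- step$product_signal[2]          # product formed per unit substrate
  eP <- exp(-acq$repetition_time_s / true_params$T1_product_s)
  S <- numeric(n); P <- numeric(n)
  s <- true_params$S0; p <- true_params$P0
  for (i in seq_len(n)) {
    S[i] <- s; P[i] <- p
    s_post <- s * cpw; p_post <- p * cpw
    s <- s_post * eS
    p <- p_post * eP + s_post * conv
  }
  out <- dynamic_series(times, S * spw, P * spw)
  attr(out, "longitudinal") <- data.frame(time_s = times, S = S, P = P)
  out
}

#' Apparent T1 implied by a true T1 under pulsed sampling
#'
#' Folds the RF-sampling loss rate into relaxation:
#' `1/T1_app = 1/T1_true + (1 - cos(pw))/TR`. With `exact = TRUE` the
#' folding uses `-ln(cos(pw))/TR` instead, under which the continuous
#' apparent-decay model reproduces the discrete pulse-by-pulse recursion
#' identically; the conventional `(1 - cos(pw))/TR` is its second-order
#' Taylor expansion (residual of order `pw^4/8` per pulse, negligible below
#' about 15 degrees).
#'
#' @param T1_true_s True longitudinal relaxation time, seconds, `> 0`.
#' @param acq An [acquisition_params()] supplying pw and TR.
#' @param exact Use the exact per-pulse folding (default `FALSE`, the
#'   conventional small-angle form).
#' @return Apparent T1 in seconds.
#' @seealso [correct_T1_apparent()] for the inverse.
#' @export
apparent_from_true_T1 <- function(T1_true_s, acq, exact = FALSE) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (any(T1_true_s <= 0)) stop("T1_true_s must be > 0")
  p <- if (exact) {
    -log(cos(acq$flip_angle_deg * pi / 180)) / acq$repetition_time_s
  } else {
    pulsing_rate(acq)
  }
  1 / (1 / T1_true_s + p)
}

#' True T1 recovered from a fitted apparent T1
#'
#' Post-hoc flip-angle correction of T1 values fitted with the pulse angle
#' set to zero: `1/T1_true = 1/T1_app - (1 - cos(pw))/TR`. Valid only while
#' relaxation dominates the apparent decay, i.e. `1/T1_app > p`.
#'
#' @param T1_apparent_s Fitted apparent T1, seconds, `> 0`.
#' @param acq An [acquisition_params()] with the *effective* flip angle used
#'   for correction.
#' @param exact Use the exact `-ln(cos(pw))/TR` folding (see
#'   [apparent_from_true_T1()]).
#' @return True T1 in seconds.
#' @export
correct_T1_apparent <- function(T1_apparent_s, acq, exact = FALSE) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (any(T1_apparent_s <= 0)) stop("T1_apparent_s must be > 0")
  p <- if (exact) {
    -log(cos(acq$flip_angle_deg * pi / 180)) / acq$repetition_time_s
  } else {
    pulsing_rate(acq)
  }
  rate <- 1 / T1_apparent_s - p
  if (any(rate <= 0))
    stop(sprintf(
      "apparent relaxation rate 1/T1_app = %.4g /s does not exceed the pulsing rate p = %.4g /s; implied true T1 is non-positive",
      min(1 / T1_apparent_s), p))
  1 / rate
}
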