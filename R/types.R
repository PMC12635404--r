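#' Acquisition parameters for pulsed hyperpolarized NMR
#'
#' Bundles the settings of a dynamic dissolution-DNP acquisition that govern
#' RF-sampling losses: each excitation pulse tips the longitudinal
#' magnetization by the effective flip angle, retaining a fraction
#' \eqn{\cos(pw)} and converting \eqn{\sin(pw)} into recorded signal. Over a
#' scan train with repetition time TR this adds an effective decay rate
#' \eqn{p = (1 - \cos pw)/TR} to both pools.
#'
#' @param flip_angle_deg Effective pulse angle in degrees, `0 <= pw < 90`.
#'   Note this is the *effective* angle; spectrometers report a nominal angle
#'   that is typically larger (see [nominal_to_effective()]).
#' @param repetition_time_s Delay between pulses (TR), seconds, `> 0`.
#' @param n_scans Number of scans in the train, `>= 2`.
#' @param t0_offset_s Time of the first scan relative to injection, seconds.
#'   Defaults to 0, i.e. the clock starts at the first recorded scan.
#' @return An object of class `acquisition_params`.
#' @seealso [pulsing_rate()], [apparent_from_true_T1()]
#' @export
acquisition_params <- function(flip_angle_deg, repetition_time_s, n_scans,
                               t0_offset_s = 0) {
  stopifnot(is.numeric(flip_angle_deg), length(flip_angle_deg) == 1L,
            is.numeric(repetition_time_s), length(repetition_time_s) == 1L,
            is.numeric(n_scans), length(n_scans) == 1L,
            is.numeric(t0_offset_s), length(t0_offset_s) == 1L)
  if (flip_angle_deg < 0 || flip_angle_deg >= 90)
    stop("flip_angle_deg must satisfy 0 <= pw < 90, got ", flip_angle_deg)
  if (repetition_time_s <= 0)
    stop("repetition_time_s must be positive")
  if (n_scans < 2 || n_scans != round(n_scans))
    stop("n_scans must be an integer >= 2")
  if (t0_offset_s < 0)
    stop("t0_offset_s must be >= 0")
  structure(
    list(flip_angle_deg = flip_angle_deg,
         repetition_time_s = repetition_time_s,
         n_scans = as.integer(n_scans),
         t0_offset_s = t0_offset_s),
    class = "acquisition_params"
  )
}

#' RF-sampling loss rate of a pulse train
#'
#' The continuous-time decay rate equivalent to losing a fraction
#' `1 - cos(pw)` of longitudinal magnetization every TR seconds:
#' `p = (1 - cos(pw)) / TR`.
#'
#' @param acq An [acquisition_params()] object.
#' @return Loss rate in 1/s.
#' @export
pulsing_rate <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  (1 - cos(acq$flip_angle_deg * pi / 180)) / acq$repetition_time_s
}

#' Map a nominal flip angle to an effective one
#'
#' Nominal spectrometer pulse angles overstate the angle actually experienced
#' by the sample (B1 inhomogeneity, miscalibration). No automatic calibration
#' is attempted; a fixed user-set factor is applied.
#'
#' @param nominal_deg Nominal flip angle, degrees.
#' @param calibration Multiplicative factor mapping nominal to effective,
#'   default 0.75 (a nominal 20 degrees acts as 15, a nominal 10 as about 8).
#' @return Effective flip angle in degrees.
#' @export
nominal_to_effective <- function(nominal_deg, calibration = 0.75) {
  stopifnot(nominal_deg >= 0, calibration > 0, calibration <= 1)
  nominal_deg * calibration
}

#' Kinetic parameters of the two-pool conversion model
#'
#' State of the unidirectional substrate-to-product model: the first-order
#' conversion rate constant `k`, the longitudinal relaxation times of the two
#' pools, and the pool amplitudes at time zero. `T1_mode` records whether the
#' T1 values are *apparent* (RF-sampling losses folded in, as obtained by
#' fitting with the pulse angle set to zero) or *true* (losses handled
#' explicitly via the acquisition parameters).
#'
#' @param k_per_s Conversion rate constant, 1/s, `>= 0`.
#' @param T1_substrate_s Substrate T1, seconds, `> 0`.
#' @param T1_product_s Product T1, seconds, `> 0`.
#' @param T1_mode `"apparent"` or `"true"`.
#' @param S0 Substrate amplitude at the first scan (arbitrary units), `>= 0`.
#' @param P0 Product amplitude at the first scan, `>= 0` (default 0: no
#'   product present at injection).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_per_s, T1_substrate_s, T1_product_s,
                           T1_mode = c("apparent", "true"),
                           S0 = 1, P0 = 0) {
  T1_mode <- match.arg(T1_mode)
  vals <- c(k_per_s = k_per_s, T1_substrate_s = T1_substrate_s,
            T1_product_s = T1_product_s, S0 = S0, P0 = P0)
  if (any(!is.finite(vals)))
    stop("kinetic parameters must be finite")
  if (k_per_s < 0) stop("k_per_s must be >= 0")
  if (T1_substrate_s <= 0 || T1_product_s <= 0) stop("T1 values must be > 0")
  if (S0 < 0 || P0 < 0) stop("initial amplitudes must be >= 0")
  structure(
    list(k_per_s = k_per_s, T1_substrate_s = T1_substrate_s,
         T1_product_s = T1_product_s, T1_mode = T1_mode, S0 = S0, P0 = P0),
    class = "kinetic_params"
  )
}

#' Time-stamped substrate/product signal traces
#'
#' The reduced form of a dynamic hyperpolarized experiment: per-scan signal
#' integrals of the substrate and product pools against time. This is the
#' input to [fit_two_pool()] and the output of the forward models and of
#' [series_to_dynamic()].
#'
#' @param times_s Strictly increasing time stamps, seconds.
#' @param substrate_signal,product_signal Signal vectors (arbitrary units),
#'   same length as `times_s`, finite.
#' @param labels Character vector of length 2 naming the pools.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(times_s, substrate_signal, product_signal,
                           labels = c(substrate = "substrate",
                                      product = "product")) {
  n <- length(times_s)
  if (length(substrate_signal) != n || length(product_signal) != n)
    stop("times, substrate and product vectors must have equal length")
  if (n >= 2 && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing")
  if (any(!is.finite(times_s)) || any(!is.finite(substrate_signal)) ||
      any(!is.finite(product_signal)))
    stop("dynamic_series values must be finite")
  structure(
    list(times_s = as.numeric(times_s),
         substrate_signal = as.numeric(substrate_signal),
         product_signal = as.numeric(product_signal),
         labels = labels),
    class = "dynamic_series"
  )
}

#' @export
as.data.frame.dynamic_series <- function(x, ...) {
  data.frame(time_s = x$times_s,
             substrate = x$substrate_signal,
             product = x$product_signal)
}

#' @export
length.dynamic_series <- function(x) length(x$times_s)

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d scans, t = %.3g..%.3g s [%s -> %s]\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              x$labels[[1]], x$labels[[2]]))
  invisible(x)
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("<acquisition_params> pw = %g deg, TR = %g s, %d scans, t0 = %g s\n",
              x$flip_angle_deg, x$repetition_time_s, x$n_scans, x$t0_offset_s))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k = %.4g /s, T1(S) = %.3g s, T1(P) = %.3g s (%s), S0 = %.3g, P0 = %.3g\n",
    x$k_per_s, x$T1_substrate_s, x$T1_product_s, x$T1_mode, x$S0, x$P0))
  invisible(x)
}
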