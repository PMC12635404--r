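# Interchange readers/writers. All text, full float precision (17
# significant digits) so write-then-read round-trips are loss-free.

.fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a dynamic series as CSV
#'
#' Plain CSV with header `time_s,substrate,product`; floats are written with
#' 17 significant digits so the round-trip is bit-stable.
#'
#' @param x A [dynamic_series()].
#' @param path File path.
#' @return `write_dynamic_series` returns `path` invisibly;
#'   `read_dynamic_series` returns a [dynamic_series()]. Columns are matched
#'   by header name, so column order is free; malformed rows are reported
#'   with their line number.
#' @export
write_dynamic_series <- function(x, path) {
  stopifnot(inherits(x, "dynamic_series"))
  df <- data.frame(time_s = .fmt(x$times_s),
                   substrate = .fmt(x$substrate_signal),
                   product = .fmt(x$product_signal))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  need <- c("time_s", "substrate", "product")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  for (cl in need) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(path, ": non-finite or non-numeric '", cl, "' at data row ",
           bad[1], " (file line ", bad[1] + 1, ")")
    df[[cl]] <- v
  }
  if (any(diff(df$time_s) <= 0))
    stop(path, ": time_s not strictly increasing at data row ",
         which(diff(df$time_s) <= 0)[1] + 1)
  dynamic_series(df$time_s, df$substrate, df$product)
}

#' Write / read a spectrum series as CSV plus JSON sidecar
#'
#' The matrix CSV has a `ppm` column followed by one column per scan
#' (points in rows); the sidecar (same path with extension `.json`) stores
#' the spectrometer frequency and scan times.
#'
#' @param x A [spectrum_series()].
#' @param path Path of the matrix CSV; the sidecar path is derived from it.
#' @return `write_spectrum_series` returns `path` invisibly;
#'   `read_spectrum_series` returns a [spectrum_series()].
#' @export
write_spectrum_series <- function(x, path) {
  stopifnot(inherits(x, "spectrum_series"))
  mat <- t(x$intensities)
  colnames(mat) <- sprintf("scan_%03d", seq_len(ncol(mat)))
  df <- data.frame(ppm = .fmt(x$ppm_axis))
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- .fmt(mat[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(
    list(freq_MHz = x$freq_MHz, scan_times_s = x$scan_times_s),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"ppm" %in% names(df)) stop(path, ": missing 'ppm' column")
  scan_cols <- grep("^scan_", names(df), value = TRUE)
  if (!length(scan_cols)) stop(path, ": no scan_* columns")
  mat <- t(as.matrix(df[scan_cols]))
  spectrum_series(as.numeric(df$ppm), mat, meta$freq_MHz,
                  as.numeric(meta$scan_times_s))
}

#' Write / read a supernatant panel as long-format CSV
#'
#' Columns `day,sample_type,metabolite,replicate,conc_mM` (extra columns
#' such as `depleted` are preserved).
#'
#' @param panel Long-format data frame (see [generate_expansion()]).
#' @param path File path.
#' @return `write_supernatant_panel` returns `path` invisibly;
#'   `read_supernatant_panel` the validated data frame.
#' @export
write_supernatant_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_supernatant_panel
#' @export
read_supernatant_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "sample_type", "metabolite", "conc_mM")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$conc_mM)))
    stop(path, ": non-finite conc_mM at data row ",
         which(!is.finite(df$conc_mM))[1])
  df
}

#' End-to-end kinetics report for one dynamic experiment
#'
#' Runs the fitting stage on a dynamic series, applies the flip-angle T1
#' correction with the effective acquisition parameters, and returns a
#' machine-readable report. Stages and parameters are embedded so the
#' report is regenerable from its inputs alone.
#'
#' @param series A [dynamic_series()].
#' @param acq [acquisition_params()] with the *effective* flip angle, used
#'   only for the post-hoc T1 correction (the fit itself sets the pulsing
#'   term to zero).
#' @param config A [fit_config()].
#' @return List with `estimates` (k, apparent and corrected T1s, S0),
#'   `standard_errors`, `r2`, `converged`, `n_points` and `provenance`
#'   (package version and a hash of the fit configuration).
#' @export
kinetics_report <- function(series, acq, config = fit_config()) {
  fit <- fit_two_pool(series, config)
  p <- fit$params_hat
  corr <- function(T1app) tryCatch(correct_T1_apparent(T1app, acq),
                                   error = function(e) NA_real_)
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(config, cfg_file)
  list(
    estimates = list(
      k_per_s = p$k_per_s,
      T1_substrate_apparent_s = p$T1_substrate_s,
      T1_product_apparent_s = p$T1_product_s,
      T1_substrate_corrected_s = corr(p$T1_substrate_s),
      T1_product_corrected_s = corr(p$T1_product_s),
      S0 = p$S0),
    standard_errors = as.list(fit$se),
    r2 = list(substrate = fit$r2_substrate, product = fit$r2_product),
    converged = fit$converged,
    n_points = fit$n_points,
    provenance = list(
      package = "hpkinetics",
      version = as.character(utils::packageVersion("hpkinetics")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      flip_angle_deg = acq$flip_angle_deg,
      repetition_time_s = acq$repetition_time_s)
  )
}

#' Write a report list as JSON (full float precision)
#' @param report A list (e.g. from [kinetics_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
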