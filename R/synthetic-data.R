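# Generators emulating the study's two data streams with embedded ground
# truth: dynamic hyperpolarized series/spectra, and 21-day supernatant
# panels from an exponentially growing, periodically re-diluted culture.

#' Scenario for a synthetic dynamic hyperpolarized experiment
#'
#' @param truth A [kinetic_params()]: the ground-truth kinetics.
#' @param acq An [acquisition_params()]: scan grid and (effective) flip
#'   angle.
#' @param noise_sd_frac Additive Gaussian noise SD on each trace as a
#'   fraction of that trace's own noiseless peak (default 0.01, the
#'   integration-noise level implied by the high per-trace goodness of fit
#'   achievable on such data). Traces with zero amplitude receive no trace
#'   noise.
#' @param render_spectra If `TRUE`, also render a [spectrum_series()] with
#'   per-scan amplitudes taken from the noiseless traces.
#' @param peaks List of two [peak_definition()] (substrate, product) used
#'   when rendering; defaults to a glucose singlet at 95 ppm and a lactate
#'   doublet (J = 55 Hz) at 183.5 ppm.
#' @param sampling `"closed_form"` (continuous apparent-decay model) or
#'   `"discrete"` (explicit pulse-by-pulse simulation; requires
#'   `truth$T1_mode = "true"`).
#' @param spectral_noise_frac Spectral-domain noise SD when rendering, as a
#'   fraction of the tallest substrate peak (default 2e-6). The rendered
#'   substrate is a single sharp line, whereas the real uniformly labelled,
#'   deuterated substrate is multiplet-split and broad; the default is
#'   chosen so the product detectability ladder of a hyperpolarized run is
#'   reproduced (strong early product, limit-of-quantification late
#'   product, zero-flux undetectable).
#' @param freq_MHz Carbon-frame spectrometer frequency for rendering
#'   (default 125.77, i.e. 13C on a 500 MHz instrument).
#' @param axis_range,axis_step ppm range and resolution of the rendered axis.
#' @param seed Integer seed; identical scenarios and seeds give
#'   byte-identical output.
#' @return An object of class `ddnp_scenario`.
#' @export
ddnp_scenario <- function(truth, acq, noise_sd_frac = 0.01,
                          render_spectra = FALSE, peaks = NULL,
                          sampling = c("closed_form", "discrete"),
                          spectral_noise_frac = 2e-6,
                          freq_MHz = 125.77,
                          axis_range = c(200, 80), axis_step = 0.02,
                          seed = 1) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(truth, "kinetic_params"),
            inherits(acq, "acquisition_params"), noise_sd_frac >= 0)
  if (is.null(peaks))
    peaks <- list(
      substrate = peak_definition("glucose", 95, c(92, 98),
                                  linewidth_Hz = 15),
      product = peak_definition("lactate", 183.5, c(181, 186),
                                multiplicity = "doublet", J_Hz = 55,
                                linewidth_Hz = 8))
  structure(
    list(truth = truth, acq = acq, noise_sd_frac = noise_sd_frac,
         render_spectra = render_spectra, peaks = peaks,
         sampling = sampling, spectral_noise_frac = spectral_noise_frac,
         freq_MHz = freq_MHz,
         axis_range = axis_range, axis_step = axis_step,
         seed = as.integer(seed)),
    class = "ddnp_scenario"
  )
}

#' Generate a synthetic dynamic series (and optionally spectra)
#'
#' Evaluates the forward model on the scan grid and adds seeded Gaussian
#' noise. If `render_spectra` is set, each scan is additionally rendered as
#' a Lorentzian spectrum whose peak amplitudes follow the noiseless traces,
#' with spectral-domain noise of the same fractional level.
#'
#' @param scenario A [ddnp_scenario()].
#' @return A [dynamic_series()] with the scenario attached as attribute
#'   `"truth"`; when `render_spectra = TRUE` the [spectrum_series()] is
#'   attached as attribute `"spectra"`.
#' @export
generate_dynamic <- function(scenario) {
  stopifnot(inherits(scenario, "ddnp_scenario"))
  acq <- scenario$acq
  times <- acq$t0_offset_s +
    (seq_len(acq$n_scans) - 1) * acq$repetition_time_s
  clean <- if (scenario$sampling == "discrete") {
    simulate_discrete_pulses(scenario$truth, acq)
  } else {
    evolve_closed_form(scenario$truth, acq, times)
  }
  speak <- max(clean$substrate_signal)
  ppeak <- max(clean$product_signal)
  out <- withr::with_seed(scenario$seed, {
    S <- clean$substrate_signal
    P <- clean$product_signal
    if (scenario$noise_sd_frac > 0) {
      if (speak > 0)
        S <- S + stats::rnorm(length(S), sd = scenario$noise_sd_frac * speak)
      if (ppeak > 0)
        P <- P + stats::rnorm(length(P), sd = scenario$noise_sd_frac * ppeak)
    }
    series <- dynamic_series(clean$times_s, S, P,
                             labels = c(substrate = scenario$peaks[[1]]$name,
                                        product = scenario$peaks[[2]]$name))
    if (scenario$render_spectra) {
      axis <- seq(max(scenario$axis_range), min(scenario$axis_range),
                  by = -scenario$axis_step)
      sub <- scenario$peaks[[1]]; prod <- scenario$peaks[[2]]
      spec_sd <- scenario$spectral_noise_frac * speak
      mat <- matrix(0, nrow = length(times), ncol = length(axis))
      for (i in seq_along(times)) {
        sub$amplitude <- clean$substrate_signal[i]
        prod$amplitude <- clean$product_signal[i]
        mat[i, ] <- synthesize_spectrum(list(sub, prod), axis,
                                        scenario$freq_MHz,
                                        noise_sd = spec_sd)
      }
      attr(series, "spectra") <- spectrum_series(axis, mat,
                                                 scenario$freq_MHz,
                                                 clean$times_s)
    }
    series
  })
  attr(out, "truth") <- scenario
  out
}

# ---------------------------------------------------------------------------
# 21-day expansion / supernatant generator

#' Default per-cell metabolic rate table
#'
#' Per-cell consumption/production rates in fmol/cell/h for the four growth
#' phases of the expansion. Values are chosen once to emulate the study's
#' qualitative pattern: near-complete glucose use through day 10 with a
#' sharp drop afterwards, heavy early lactate export that collapses in the
#' decline phase, sustained dipeptide (GlutaMAX) cleavage, early amino-acid
#' consumption, and late accumulation of TCA intermediates.
#'
#' @return Data frame with columns `metabolite`, `direction`
#'   (`"consumed"`/`"produced"`) and the phase rates `lag`, `ramp`, `burst`,
#'   `decline`.
#' @export
default_rate_table <- function() {
  tab <- rbind(
    c("glucose",       "consumed", 125,  315,  36,   40),
    c("glutamax",      "consumed", 22,   62,   54,   75),
    c("glutamine",     "consumed", 1,    8,    4,    2),
    c("arginine",      "consumed", 5,    25,   9,    4),
    c("histidine",     "consumed", 0.2,  1.3,  0.5,  0.2),
    c("isoleucine",    "consumed", 1.3,  7,    3,    1.5),
    c("leucine",       "consumed", 1.3,  7,    3,    1.5),
    c("phenylalanine", "consumed", 0.2,  1.2,  0.5,  0.2),
    c("tyrosine",      "consumed", 0.25, 1.4,  0.6,  0.2),
    c("valine",        "consumed", 0.6,  3.3,  1.4,  0.7),
    c("lactate",       "produced", 200,  500,  80,   25),
    c("pyruvate",      "produced", 10,   30,   15,   2),
    c("formate",       "produced", 2,    5,    1,    4),
    c("succinate",     "produced", 0.3,  0.5,  0.5,  3),
    c("fumarate",      "produced", 0.1,  0.2,  0.2,  1.5),
    c("alanine",       "produced", 15,   50,   40,   60))
  out <- data.frame(metabolite = tab[, 1], direction = tab[, 2],
                    lag = as.numeric(tab[, 3]), ramp = as.numeric(tab[, 4]),
                    burst = as.numeric(tab[, 5]),
                    decline = as.numeric(tab[, 6]),
                    stringsAsFactors = FALSE)
  out
}

#' Default fresh-medium composition
#'
#' Formulation-typical concentrations (mM) for a glucose/GlutaMAX RPMI-style
#' expansion medium; produced species carry small trace levels.
#'
#' @return Named numeric vector, mM.
#' @export
default_fresh_medium <- function() {
  c(glucose = 11.1, glutamax = 2.0, glutamine = 0.3, arginine = 1.1,
    histidine = 0.097, isoleucine = 0.38, leucine = 0.38,
    phenylalanine = 0.091, tyrosine = 0.11, valine = 0.17,
    lactate = 0.2, pyruvate = 0.05, formate = 0.02, succinate = 0.01,
    fumarate = 0.005, alanine = 0.05)
}

#' Scenario for the 21-day CAR T expansion culture
#'
#' Cells are seeded on day 0 and, from day 3, counted and re-diluted to the
#' target density every second day; supernatant (spent) and fresh-medium
#' blanks are sampled at each feed. Growth is piecewise exponential over
#' four phases (lag up to day 3, ramp to day 10, burst to day 12, decline
#' thereafter) and metabolite exchange is proportional to the integrated
#' cell-hours of each feed interval with phase-dependent per-cell rates.
#'
#' @param feed_days Dilution/sampling days (default 3, 5, ..., 21).
#' @param target_density Post-dilution density, cells/mL (default 0.5e6).
#' @param initial_density Seeding density on day 0, cells/mL (default 1e6).
#' @param phase_bounds Named numeric: end day of `lag`, `ramp`, `burst`
#'   (decline runs to the last feed).
#' @param growth_rates Named numeric: per-hour exponential growth rate of
#'   each phase.
#' @param rate_table Per-cell rate table as from [default_rate_table()],
#'   fmol/cell/h.
#' @param fresh_medium Named mM vector as from [default_fresh_medium()].
#' @param noise_cv Multiplicative (log-normal) measurement noise CV
#'   (default 0.03).
#' @param n_replicates Biological replicates sharing the truth and
#'   differing only in noise (default 3).
#' @param seed Integer seed.
#' @return An object of class `expansion_scenario`.
#' @export
expansion_scenario <- function(feed_days = seq(3, 21, by = 2),
                               target_density = 0.5e6,
                               initial_density = 1e6,
                               phase_bounds = c(lag = 3, ramp = 10,
                                                burst = 12),
                               growth_rates = c(lag = 0.002, ramp = 0.010,
                                                burst = 0.029,
                                                decline = 0.002),
                               rate_table = default_rate_table(),
                               fresh_medium = default_fresh_medium(),
                               noise_cv = 0.03, n_replicates = 3,
                               seed = 1) {
  stopifnot(all(diff(feed_days) > 0), target_density > 0,
            initial_density > 0, noise_cv >= 0, n_replicates >= 1)
  if (!all(c("lag", "ramp", "burst") %in% names(phase_bounds)))
    stop("phase_bounds must name lag, ramp and burst end days")
  if (!all(c("lag", "ramp", "burst", "decline") %in% names(growth_rates)))
    stop("growth_rates must name all four phases")
  if (any(rate_table[, c("lag", "ramp", "burst", "decline")] < 0))
    stop("per-cell rates must be >= 0")
  missing_fresh <- setdiff(rate_table$metabolite, names(fresh_medium))
  if (length(missing_fresh))
    stop("fresh_medium lacks: ", paste(missing_fresh, collapse = ", "))
  structure(
    list(feed_days = feed_days, target_density = target_density,
         initial_density = initial_density, phase_bounds = phase_bounds,
         growth_rates = growth_rates, rate_table = rate_table,
         fresh_medium = fresh_medium, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "expansion_scenario"
  )
}

# growth phase containing time point `day`
.phase_of <- function(day, bounds) {
  if (day < bounds[["lag"]]) "lag"
  else if (day < bounds[["ramp"]]) "ramp"
  else if (day < bounds[["burst"]]) "burst"
  else "decline"
}

# integrate N(t) dt (cell-hours/mL) and final density over [d0, d1] days,
# piecewise-exponential across phase boundaries
.grow_interval <- function(n0, d0, d1, scenario) {
  bounds <- scenario$phase_bounds
  cuts <- sort(unique(c(d0, d1,
                        bounds[bounds > d0 & bounds < d1])))
  ch <- 0; n <- n0
  for (i in seq_len(length(cuts) - 1)) {
    h <- (cuts[i + 1] - cuts[i]) * 24
    g <- scenario$growth_rates[[.phase_of(cuts[i], bounds)]]
    if (abs(g) < 1e-12) {
      ch <- ch + n * h
    } else {
      ch <- ch + n * (exp(g * h) - 1) / g
      n <- n * exp(g * h)
    }
  }
  list(cell_hours = ch, density = n)
}

#' Generate a synthetic 21-day supernatant panel
#'
#' Between feeds the culture grows exponentially at the phase rate; each
#' metabolite's spent concentration is the fresh value minus (consumed) or
#' plus (produced) the phase rate times the integrated cell-hours of the
#' interval, floored at zero with a depletion flag for consumed species.
#' At each feed, concentrations reset to fresh medium and the density to the
#' target. Measurement noise is multiplicative log-normal with the scenario
#' CV, applied independently to every spent and fresh reading of every
#' replicate.
#'
#' @param scenario An [expansion_scenario()].
#' @return A list of class `expansion_panel`: `$panel`, a long-format data
#'   frame (`day`, `sample_type`, `metabolite`, `replicate`, `conc_mM`,
#'   `depleted`) directly consumable by [assemble_timecourse()];
#'   `$cells`, the true per-feed-day count trajectory with pre- and
#'   post-dilution densities and the population increase factor; and
#'   `$truth`, the scenario (embedded ground truth).
#' @export
generate_expansion <- function(scenario = expansion_scenario()) {
  stopifnot(inherits(scenario, "expansion_scenario"))
  days <- scenario$feed_days
  prev <- c(0, days[-length(days)])
  # true interval quantities (shared by all replicates)
  n0 <- scenario$initial_density
  intervals <- vector("list", length(days))
  cells <- data.frame(day = days, pre_feed = NA_real_, post_feed = NA_real_,
                      pif = NA_real_)
  for (i in seq_along(days)) {
    gr <- .grow_interval(n0, prev[i], days[i], scenario)
    mid <- (prev[i] + days[i]) / 2
    phase <- .phase_of(mid, scenario$phase_bounds)
    rates <- scenario$rate_table[[phase]]
    delta <- rates * gr$cell_hours * 1e-9   # fmol/cell/h * cell*h/mL -> mM
    fresh <- scenario$fresh_medium[scenario$rate_table$metabolite]
    spent <- ifelse(scenario$rate_table$direction == "consumed",
                    pmax(fresh - delta, 0), fresh + delta)
    intervals[[i]] <- data.frame(
      metabolite = scenario$rate_table$metabolite,
      fresh_true = unname(fresh), spent_true = unname(spent),
      depleted = scenario$rate_table$direction == "consumed" &
        (fresh - delta) < 0,
      stringsAsFactors = FALSE)
    cells$pre_feed[i] <- gr$density
    cells$post_feed[i] <- scenario$target_density
    cells$pif[i] <- population_increase_factor(
      gr$density, if (i == 1) n0 else scenario$target_density)
    n0 <- scenario$target_density
  }
  cv <- scenario$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2   # unit-mean log-normal noise
  panel <- withr::with_seed(scenario$seed, {
    rows <- list()
    for (i in seq_along(days)) {
      iv <- intervals[[i]]
      for (r in seq_len(scenario$n_replicates)) {
        nm <- nrow(iv)
        fnoise <- if (cv > 0) stats::rlnorm(nm, meanlog, sdlog) else rep(1, nm)
        snoise <- if (cv > 0) stats::rlnorm(nm, meanlog, sdlog) else rep(1, nm)
        rows[[length(rows) + 1L]] <- data.frame(
          day = days[i], sample_type = "fresh", metabolite = iv$metabolite,
          replicate = r, conc_mM = iv$fresh_true * fnoise,
          depleted = FALSE, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          day = days[i], sample_type = "spent", metabolite = iv$metabolite,
          replicate = r, conc_mM = iv$spent_true * snoise,
          depleted = iv$depleted, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  structure(list(panel = panel, cells = cells, truth = scenario),
            class = "expansion_panel")
}

# ---------------------------------------------------------------------------
# Preset library

.preset_names <- c("fig1a_pyruvate", "fig1b_glucose", "day7", "day14",
                   "day21_pyruvate", "expansion_default")

#' Named scenario presets at the study's reported operating points
#'
#' Each dynamic preset carries the fitted apparent kinetics reported for
#' that experiment as ground truth, with the effective flip angle, TR and a
#' scan train long enough to cover the hyperpolarized signal lifetime:
#' \describe{
#'   \item{fig1a_pyruvate}{pyruvate-to-lactate in day-5 activated T cells:
#'     k = 10.7e-5 /s, apparent T1 30/16 s, effective pw 8 deg, TR 2 s.}
#'   \item{fig1b_glucose}{glucose-to-lactate, day-5 T cells: k = 9.4e-5 /s,
#'     apparent T1 10/18 s, effective pw 15 deg, TR 2 s.}
#'   \item{day7}{CAR T glucose run, expansion day 7: k = 5.278e-5 /s,
#'     apparent T1 9/17 s, effective pw 15 deg (nominal 20), TR 1 s.}
#'   \item{day14}{as day7 with k = 1.146e-5 /s.}
#'   \item{day21_pyruvate}{low-flux late-expansion pyruvate run: apparent
#'     T1 28/15 s, effective pw 8 deg (nominal 10), TR 1 s; k set to an
#'     eighth of the day-14 rate, mirroring the summed-spectra fold change.}
#'   \item{expansion_default}{the default [expansion_scenario()].}
#' }
#'
#' @param name Preset name; unknown names raise an error listing the valid
#'   presets.
#' @param seed Seed stored in the returned scenario (default 1).
#' @return A [ddnp_scenario()] or [expansion_scenario()].
#' @export
hp_preset <- function(name, seed = 1) {
  if (!name %in% .preset_names)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(.preset_names, collapse = ", "))
  switch(
    name,
    fig1a_pyruvate = ddnp_scenario(
      truth = kinetic_params(10.7e-5, 30, 16, "apparent", S0 = 1),
      acq = acquisition_params(8, 2, 120), seed = seed,
      peaks = list(
        substrate = peak_definition("pyruvate", 171, c(169, 173),
                                    linewidth_Hz = 8),
        product = peak_definition("lactate", 183.5, c(181, 186),
                                  linewidth_Hz = 8))),
    fig1b_glucose = ddnp_scenario(
      truth = kinetic_params(9.4e-5, 10, 18, "apparent", S0 = 1),
      acq = acquisition_params(15, 2, 120), seed = seed),
    day7 = ddnp_scenario(
      truth = kinetic_params(5.278e-5, 9, 17, "apparent", S0 = 1),
      acq = acquisition_params(15, 1, 180), seed = seed),
    day14 = ddnp_scenario(
      truth = kinetic_params(1.146e-5, 9, 17, "apparent", S0 = 1),
      acq = acquisition_params(15, 1, 180), seed = seed),
    day21_pyruvate = ddnp_scenario(
      truth = kinetic_params(1.146e-5 / 8, 28, 15, "apparent", S0 = 1),
      acq = acquisition_params(8, 1, 240), seed = seed,
      peaks = list(
        substrate = peak_definition("pyruvate", 171, c(169, 173),
                                    linewidth_Hz = 8),
        product = peak_definition("lactate", 183.5, c(181, 186),
                                  linewidth_Hz = 8))),
    expansion_default = expansion_scenario(seed = seed)
  )
}

#' @rdname hp_preset
#' @export
preset_library <- function(seed = 1) {
  out <- lapply(.preset_names, hp_preset, seed = seed)
  names(out) <- .preset_names
  out
}
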