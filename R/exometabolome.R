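# DSS-referenced quantification of culture-medium metabolites and
# feed-schedule-aware consumption/production time courses.

#' Internal-standard reference for absolute quantification
#'
#' Describes the DSS-containing buffer and the mixing step: a sample aliquot
#' is mixed with a buffer whose DSS concentration is known, so the DSS
#' concentration in the tube and the dilution of the sample follow from the
#' volumes.
#'
#' @param dss_buffer_conc_mM DSS concentration in the buffer, mM
#'   (default 0.644).
#' @param sample_volume_uL Sample aliquot volume, microlitres (default 500).
#' @param buffer_volume_uL Buffer volume added, microlitres (default 100).
#' @param dss_protons Protons under the DSS reference singlet (default 9,
#'   the trimethylsilyl group).
#' @return An object of class `quant_reference`.
#' @export
quant_reference <- function(dss_buffer_conc_mM = 0.644,
                            sample_volume_uL = 500,
                            buffer_volume_uL = 100,
                            dss_protons = 9) {
  stopifnot(dss_buffer_conc_mM > 0, sample_volume_uL > 0,
            buffer_volume_uL > 0, dss_protons >= 1)
  structure(
    list(dss_buffer_conc_mM = dss_buffer_conc_mM,
         sample_volume_uL = sample_volume_uL,
         buffer_volume_uL = buffer_volume_uL,
         dss_protons = dss_protons),
    class = "quant_reference"
  )
}

#' DSS concentration in the measurement tube
#' @param ref A [quant_reference()].
#' @return mM of DSS after mixing.
#' @export
dss_tube_conc <- function(ref = quant_reference()) {
  ref$dss_buffer_conc_mM * ref$buffer_volume_uL /
    (ref$sample_volume_uL + ref$buffer_volume_uL)
}

#' Absolute metabolite concentration from a DSS-referenced integral
#'
#' Per-proton integrals are compared: the metabolite concentration in the
#' tube is `(integral/n_protons) / (dss_integral/dss_protons)` times the DSS
#' tube concentration, and the returned value is back-calculated to the
#' original (pre-mixing) sample frame by dividing by the sample dilution
#' `sample_vol / (sample_vol + buffer_vol)`.
#'
#' @param integral Metabolite peak integral(s), arbitrary units (vectorized).
#' @param n_protons Protons under the quantified peak(s), `>= 1`.
#' @param dss_integral DSS reference integral, same units, `> 0`.
#' @param ref A [quant_reference()].
#' @return Concentration(s) in mM in the original sample.
#' @export
quantify <- function(integral, n_protons, dss_integral,
                     ref = quant_reference()) {
  stopifnot(inherits(ref, "quant_reference"))
  if (any(dss_integral <= 0)) stop("dss_integral must be > 0")
  if (any(n_protons < 1)) stop("n_protons must be >= 1")
  dilution <- ref$sample_volume_uL /
    (ref$sample_volume_uL + ref$buffer_volume_uL)
  tube <- (integral / n_protons) / (dss_integral / ref$dss_protons) *
    dss_tube_conc(ref)
  tube / dilution
}

#' Consumption of a metabolite between fresh and spent medium
#'
#' @param fresh_mM Concentration in fresh medium, mM, `> 0`.
#' @param spent_mM Concentration in spent medium, mM.
#' @return Data frame with `consumed_mM` (fresh - spent; negative means the
#'   metabolite was produced), `consumed_fraction` (consumed/fresh) and the
#'   logical `production` flag.
#' @export
consumption <- function(fresh_mM, spent_mM) {
  if (any(fresh_mM <= 0)) stop("fresh_mM must be > 0")
  consumed <- fresh_mM - spent_mM
  data.frame(consumed_mM = consumed,
             consumed_fraction = consumed / fresh_mM,
             production = consumed < 0)
}

#' Population increase factor between counts
#'
#' `(new - previous) / previous`: 1 means the culture doubled since the last
#' count, 0 means no growth, negative values mean net cell loss.
#'
#' @param new_count,prev_count Cell counts; `prev_count > 0`.
#' @return Unitless factor.
#' @export
population_increase_factor <- function(new_count, prev_count) {
  if (any(prev_count <= 0)) stop("previous count must be > 0")
  (new_count - prev_count) / prev_count
}

#' Default proton counts for the quantified medium metabolites
#'
#' One resolved peak is quantified per metabolite; the table records the
#' number of protons under that peak. These are conventions for the default
#' panel and are overridable by the caller.
#'
#' @return Named numeric vector of proton counts.
#' @export
default_proton_table <- function() {
  c(glucose = 1,       # alpha-anomeric H1 doublet
    lactate = 3,       # CH3
    alanine = 3,       # CH3
    pyruvate = 3,      # CH3
    formate = 1,       # CH
    succinate = 4,     # 2 x CH2
    fumarate = 2,      # 2 x CH
    glutamine = 2,     # gamma-CH2
    glutamax = 3,      # alanyl CH3 of the dipeptide
    histidine = 1,     # ring H
    isoleucine = 3,    # delta-CH3
    leucine = 6,       # 2 x delta-CH3
    phenylalanine = 2, # ortho ring H
    tyrosine = 2,      # 3,5 ring H
    valine = 3,        # one CH3 doublet
    arginine = 2)      # delta-CH2
}

#' Assemble per-metabolite consumption time courses
#'
#' Pairs spent-medium samples with the same-day fresh-medium blanks and
#' aggregates replicates into mean and SD per metabolite and day. Spent
#' samples without a same-day blank are reported, never imputed.
#'
#' @param samples Data frame in long format with columns `day`,
#'   `sample_type` (`"spent"` or `"fresh"`), `metabolite`, `conc_mM` and
#'   optionally `replicate`. Fresh blanks are matched by day and metabolite
#'   (averaged across their replicates).
#' @return An object of class `consumption_timecourse`: `$profiles`, a tidy
#'   data frame (`metabolite`, `day`, `n`, `fresh_mM`, `spent_mean`,
#'   `spent_sd`, `consumed_mean`, `consumed_sd`, `fraction_mean`,
#'   `fraction_sd`, `production`), sorted by metabolite then day; and
#'   `$orphans`, the spent samples lacking a blank.
#' @export
assemble_timecourse <- function(samples) {
  req <- c("day", "sample_type", "metabolite", "conc_mM")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(samples$sample_type %in% c("spent", "fresh")))
    stop("sample_type must be 'spent' or 'fresh'")
  if (is.null(samples$replicate)) samples$replicate <- 1L
  fresh <- samples[samples$sample_type == "fresh", ]
  spent <- samples[samples$sample_type == "spent", ]
  fresh_mean <- stats::aggregate(conc_mM ~ day + metabolite, data = fresh,
                                 FUN = mean)
  names(fresh_mean)[names(fresh_mean) == "conc_mM"] <- "fresh_mM"
  merged <- merge(spent, fresh_mean, by = c("day", "metabolite"),
                  all.x = TRUE)
  orphans <- merged[is.na(merged$fresh_mM),
                    c("day", "metabolite", "replicate", "conc_mM")]
  merged <- merged[!is.na(merged$fresh_mM), ]
  if (nrow(merged) == 0L)
    return(structure(list(profiles = NULL, orphans = orphans),
                     class = "consumption_timecourse"))
  merged$consumed <- merged$fresh_mM - merged$conc_mM
  merged$fraction <- merged$consumed / merged$fresh_mM
  agg <- function(col, fun) {
    out <- stats::aggregate(merged[[col]],
                            by = list(metabolite = merged$metabolite,
                                      day = merged$day),
                            FUN = fun)
    out$x
  }
  keys <- stats::aggregate(merged$conc_mM,
                           by = list(metabolite = merged$metabolite,
                                     day = merged$day),
                           FUN = length)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  profiles <- data.frame(
    metabolite = keys$metabolite, day = keys$day, n = keys$x,
    fresh_mM = agg("fresh_mM", mean),
    spent_mean = agg("conc_mM", mean), spent_sd = agg("conc_mM", sd0),
    consumed_mean = agg("consumed", mean), consumed_sd = agg("consumed", sd0),
    fraction_mean = agg("fraction", mean), fraction_sd = agg("fraction", sd0),
    stringsAsFactors = FALSE)
  profiles$production <- profiles$consumed_mean < 0
  profiles <- profiles[order(profiles$metabolite, profiles$day), ]
  rownames(profiles) <- NULL
  structure(list(profiles = profiles, orphans = orphans),
            class = "consumption_timecourse")
}

#' @export
print.consumption_timecourse <- function(x, ...) {
  if (is.null(x$profiles)) {
    cat("<consumption_timecourse> empty (no paired samples)\n")
  } else {
    cat(sprintf("<consumption_timecourse> %d metabolites x %d days",
                length(unique(x$profiles$metabolite)),
                length(unique(x$profiles$day))))
    if (nrow(x$orphans)) cat(sprintf(", %d orphan spent samples",
                                     nrow(x$orphans)))
    cat("\n")
  }
  invisible(x)
}
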