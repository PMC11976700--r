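#' Indicator calibration for the ratiometric pH assay
#'
#' Bromothymol blue (BTB) interconverts between a protonated (yellow) and a
#' deprotonated (blue) form. Absorbance at a reporter wavelength (616 nm,
#' where only the blue form absorbs strongly) divided by absorbance at the
#' isosbestic wavelength (499 nm, where both forms absorb equally) is a
#' concentration- and path-length-invariant measure of the deprotonation
#' state. The calibration holds the two limiting ratios and the indicator's
#' apparent pKa in the (methanolic) read mixture; all three are empirical
#' per-batch quantities, never hard-coded chemistry.
#'
#' @param pka_apparent Apparent pKa of the indicator in the read mixture
#'   (pH units). The 50% methanol quench shifts it away from the aqueous
#'   literature value, so it must come from calibration.
#' @param ratio_acid A_report/A_iso for the fully protonated indicator.
#' @param ratio_base A_report/A_iso for the fully deprotonated indicator;
#'   must exceed `ratio_acid`.
#' @param report_wavelength,iso_wavelength Wavelengths in nm (metadata).
#' @param indicator_conc Indicator concentration in the read mixture (mM),
#'   used only when minor buffering terms are requested.
#' @return An object of class `indicator_calibration`.
#' @export
indicator_calibration <- function(pka_apparent = 7.10,
                                  ratio_acid = 0.10,
                                  ratio_base = 2.00,
                                  report_wavelength = 616,
                                  iso_wavelength = 499,
                                  indicator_conc = 0.032) {
  stopifnot_number(pka_apparent, "pka_apparent", 2, 12)
  stopifnot_number(ratio_acid, "ratio_acid", 0, Inf)
  stopifnot_number(ratio_base, "ratio_base", 0, Inf)
  stopifnot_number(indicator_conc, "indicator_conc", 0, Inf)
  if (ratio_base <= ratio_acid)
    halocat_error("ratio_base must exceed ratio_acid", "halocat_invalid_parameter")
  if (report_wavelength == iso_wavelength)
    halocat_error("report and isosbestic wavelengths must differ",
                  "halocat_invalid_parameter")
  structure(list(pka_apparent = pka_apparent, ratio_acid = ratio_acid,
                 ratio_base = ratio_base, report_wavelength = report_wavelength,
                 iso_wavelength = iso_wavelength, indicator_conc = indicator_conc),
            class = "indicator_calibration")
}

#' Buffer specification
#'
#' Weak-acid buffer in the read mixture. `total_conc` is the concentration
#' after quench dilution (e.g. 2 mM MOPS reaction buffer quenched 1:1 with
#' methanolic indicator gives 1 mM in the mixture).
#'
#' @param total_conc Total buffer concentration in the read mixture (mM).
#' @param pka_apparent Apparent pKa in the read mixture (pH units).
#' @param initial_ph Reaction pH at time zero.
#' @return An object of class `buffer_spec`.
#' @export
buffer_spec <- function(total_conc, pka_apparent = 7.20, initial_ph = 7.00) {
  stopifnot_number(total_conc, "total_conc", 0, Inf, c(FALSE, TRUE))
  stopifnot_number(pka_apparent, "pka_apparent", 2, 12)
  stopifnot_number(initial_ph, "initial_ph", 2, 12)
  structure(list(total_conc = total_conc, pka_apparent = pka_apparent,
                 initial_ph = initial_ph),
            class = "buffer_spec")
}

#' Assay scenario
#'
#' Everything needed to turn two-wavelength plate reads into product
#' concentrations for one reaction setup. Buffer and indicator concentrations
#' are expressed in the read mixture; product is reported in the original
#' sample via `dilution_factor` (default 2 for the 1:1 methanolic quench).
#'
#' @param buffer A [buffer_spec()].
#' @param calibration An [indicator_calibration()].
#' @param substrate0 Initial substrate concentration in the sample (mM).
#' @param enzyme_loading Enzyme concentration (mg/mL), used downstream for
#'   specific activities.
#' @param dilution_factor Sample-to-read-mixture dilution (>= 1).
#' @param temperature Assay temperature in degrees C (metadata; calibration
#'   must be performed at this temperature).
#' @return An object of class `assay_scenario`.
#' @export
assay_scenario <- function(buffer, calibration, substrate0,
                           enzyme_loading = 0.05, dilution_factor = 2,
                           temperature = 30) {
  if (!inherits(buffer, "buffer_spec"))
    halocat_error("`buffer` must be a buffer_spec", "halocat_invalid_parameter")
  if (!inherits(calibration, "indicator_calibration"))
    halocat_error("`calibration` must be an indicator_calibration",
                  "halocat_invalid_parameter")
  stopifnot_number(substrate0, "substrate0", 0, Inf, c(FALSE, TRUE))
  stopifnot_number(enzyme_loading, "enzyme_loading", 0, Inf)
  stopifnot_number(dilution_factor, "dilution_factor", 1, Inf)
  structure(list(buffer = buffer, calibration = calibration,
                 substrate0 = substrate0, enzyme_loading = enzyme_loading,
                 dilution_factor = dilution_factor, temperature = temperature),
            class = "assay_scenario")
}

#' Per-well two-wavelength time series
#'
#' @param well_id Well label.
#' @param time_s Times in seconds (nondecreasing).
#' @param a_report Absorbance at the reporter wavelength.
#' @param a_iso Absorbance at the isosbestic wavelength (> 0).
#' @return A data frame of class `well_timeseries`.
#' @export
well_timeseries <- function(well_id, time_s, a_report, a_iso) {
  if (length(time_s) != length(a_report) || length(time_s) != length(a_iso))
    halocat_error("time_s, a_report, a_iso must have equal length",
                  "halocat_invalid_parameter")
  if (is.unsorted(time_s))
    halocat_error("times must be nondecreasing", "halocat_invalid_parameter")
  if (!all(is.finite(a_report)) || !all(is.finite(a_iso)))
    halocat_error("absorbances must be finite", "halocat_invalid_read")
  if (any(a_iso <= 0))
    halocat_error("isosbestic absorbance must be positive", "halocat_invalid_read")
  structure(data.frame(time_s = time_s, a_report = a_report, a_iso = a_iso),
            well_id = as.character(well_id),
            class = c("well_timeseries", "data.frame"))
}

#' Product progress curve
#'
#' Product concentration (mM, in the original sample) versus time. Values
#' exceeding `substrate0` are possible under read noise; they are flagged in
#' the `over_range` column, never clamped, so rate fits see unbiased noise.
#'
#' @param time_s Times (s).
#' @param product Product concentrations (mM).
#' @param uncertainty Per-point uncertainty (mM), NA when unknown.
#' @param substrate0 Initial substrate concentration (mM).
#' @param label Curve label.
#' @return A data frame of class `progress_curve` with attributes
#'   `substrate0` and `label`.
#' @export
progress_curve <- function(time_s, product, uncertainty = NA_real_,
                           substrate0, label = "") {
  stopifnot_number(substrate0, "substrate0", 0, Inf, c(FALSE, TRUE))
  structure(data.frame(time_s = time_s, product = product,
                       uncertainty = uncertainty,
                       over_range = product > substrate0),
            substrate0 = substrate0, label = as.character(label),
            class = c("progress_curve", "data.frame"))
}

#' Isosbestic (isometric) normalization of a two-wavelength read
#'
#' Converts a reporter/isosbestic absorbance pair into the deprotonated
#' fraction f of the indicator. Because both absorbances scale identically
#' with indicator concentration and optical path length, the ratio, and hence
#' f, is invariant to dilution and meniscus effects.
#'
#' @param a_report,a_iso Absorbances (vectors of equal length).
#' @param cal An [indicator_calibration()].
#' @return Fraction(s) in `[1e-4, 1 - 1e-4]` (clamped; out-of-range ratios
#'   beyond 5% of the calibrated span additionally raise a warning).
#' @export
isometric_normalize <- function(a_report, a_iso, cal) {
  if (any(!is.finite(a_iso)) || any(a_iso <= 0))
    halocat_error("isosbestic absorbance must be positive and finite",
                  "halocat_invalid_read")
  r <- a_report / a_iso
  span <- cal$ratio_base - cal$ratio_acid
  tol <- 0.05 * span
  if (any(r < cal$ratio_acid - tol | r > cal$ratio_base + tol))
    halocat_warn("absorbance ratio outside calibrated range; clamping",
                 "halocat_out_of_range")
  f <- (r - cal$ratio_acid) / span
  pmin(pmax(f, 1e-4), 1 - 1e-4)
}

#' pH from the indicator deprotonation fraction
#'
#' Henderson-Hasselbalch on the indicator: pH = pKa + log10(f/(1-f)).
#'
#' @param f Deprotonated fraction(s), strictly inside (0, 1).
#' @param cal An [indicator_calibration()].
#' @return pH value(s).
#' @export
ph_from_fraction <- function(f, cal) {
  if (any(f <= 0 | f >= 1))
    halocat_error("fraction must lie strictly inside (0, 1)",
                  "halocat_domain_error")
  cal$pka_apparent + log10(f / (1 - f))
}

#' Indicator deprotonation fraction at a given pH (inverse of
#' [ph_from_fraction()])
#'
#' @param ph pH value(s).
#' @param cal An [indicator_calibration()].
#' @return Fraction(s) in (0, 1).
#' @export
fraction_from_ph <- function(ph, cal) {
  1 / (1 + 10^(cal$pka_apparent - ph))
}

# Ionized fraction of a monoprotic weak-acid buffer.
buffer_alpha <- function(ph, pka) 1 / (1 + 10^(pka - ph))

#' Protons consumed between two pH values, via buffer capacity
#'
#' The dominant proton reservoir in a dilute buffer is the buffer itself:
#' moving from `ph_start` to `ph_end` consumes
#' `B * (alpha(ph_end) - alpha(ph_start))` mM protons, where alpha is the
#' ionized fraction of the buffer. With `include_minor_terms` the indicator's
#' own deprotonation and the change in free proton concentration are added;
#' both are negligible against a 1-2 mM buffer but exposed for completeness.
#' Positive when the pH rises (protons consumed by the reaction).
#'
#' @param ph_start,ph_end pH values, each in `[3, 11]`.
#' @param buffer A [buffer_spec()] (concentration in the read mixture).
#' @param cal An [indicator_calibration()]; required only when
#'   `include_minor_terms = TRUE`.
#' @param include_minor_terms Add indicator self-buffering and free-proton
#'   terms (default FALSE).
#' @return Consumed protons in mM (read-mixture basis).
#' @export
protons_consumed <- function(ph_start, ph_end, buffer, cal = NULL,
                             include_minor_terms = FALSE) {
  if (any(c(ph_start, ph_end) < 3) || any(c(ph_start, ph_end) > 11))
    halocat_error("pH must be within [3, 11]", "halocat_domain_error")
  dn <- buffer$total_conc *
    (buffer_alpha(ph_end, buffer$pka_apparent) -
       buffer_alpha(ph_start, buffer$pka_apparent))
  if (include_minor_terms) {
    if (is.null(cal))
      halocat_error("minor terms need an indicator calibration",
                    "halocat_invalid_parameter")
    dn <- dn + cal$indicator_conc *
      (fraction_from_ph(ph_end, cal) - fraction_from_ph(ph_start, cal))
    dn <- dn + (10^(-ph_start) - 10^(-ph_end)) * 1e3  # mol/L -> mM
  }
  dn
}

#' Quantify a plate time series into a progress curve
#'
#' Composes the full quantification chain per reading: isosbestic
#' normalization, indicator equilibrium (pH), buffer capacity (consumed
#' protons), and the quench dilution. One proton is consumed per ring-opening
#' event (strong acid converted to a weak acid), so consumed protons equal
#' product formed. The first reading defines the t = 0 reference state;
#' monotonicity is not enforced, so read noise passes through unbiased.
#'
#' @param ts A [well_timeseries()] (>= 2 readings).
#' @param scenario An [assay_scenario()].
#' @param include_minor_terms Passed to [protons_consumed()].
#' @return A [progress_curve()] in original-sample mM.
#' @export
quantify_timeseries <- function(ts, scenario, include_minor_terms = FALSE) {
  if (nrow(ts) < 2L)
    halocat_error("need at least two readings (first defines the reference)",
                  "halocat_insufficient_data")
  well <- attr(ts, "well_id")
  ph <- withCallingHandlers(
    ph_from_fraction(isometric_normalize(ts$a_report, ts$a_iso,
                                         scenario$calibration),
                     scenario$calibration),
    halocat_warning = function(w) {
      halocat_warn(sprintf("well %s: %s", well, conditionMessage(w)),
                   "halocat_out_of_range")
      invokeRestart("muffleWarning")
    })
  # clamped extreme reads imply a pH just outside the buffer-capacity
  # domain; pin them to its boundary (they are flagged by the clamp warning)
  ph <- pmin(pmax(ph, 3), 11)
  dn <- vapply(ph, function(p)
    protons_consumed(ph[1], p, scenario$buffer, scenario$calibration,
                     include_minor_terms), numeric(1))
  progress_curve(ts$time_s, scenario$dilution_factor * dn,
                 substrate0 = scenario$substrate0,
                 label = if (is.null(well)) "" else well)
}
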