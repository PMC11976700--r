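#' Fit a linear halide standard curve
#'
#' Ordinary least squares of absorbance (460 nm, ferric-thiocyanate readout)
#' on halide concentration. The intercept is fitted, not forced through
#' zero: the assay reagent blank has nonzero absorbance and batches differ.
#' A fit with r-squared below 0.98 raises a warning.
#'
#' @param conc Standard concentrations (mM, >= 3 distinct values).
#' @param a460 Absorbances at 460 nm.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `valid_range`, `points`.
#' @export
fit_standard_curve <- function(conc, a460) {
  if (length(conc) != length(a460))
    halocat_error("conc and a460 must have equal length",
                  "halocat_invalid_parameter")
  if (length(unique(conc)) < 3L)
    halocat_error("need at least 3 distinct standard concentrations",
                  "halocat_degenerate_design")
  fit <- stats::lm(a460 ~ conc)
  r2 <- quiet_lm_summary(fit)$r.squared
  if (r2 < 0.98)
    halocat_warn(sprintf("standard curve r-squared = %.4f < 0.98", r2),
                 "halocat_poor_calibration")
  slope <- unname(stats::coef(fit)["conc"])
  if (slope <= 0)
    halocat_error("standard curve slope must be positive",
                  "halocat_invalid_curve")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2,
                 valid_range = c(0, max(conc)),
                 points = data.frame(conc = conc, a460 = a460)),
            class = "standard_curve")
}

#' Halide concentration from an absorbance reading
#'
#' Inverts the standard line: `(A460 - intercept) / slope`. Readings mapping
#' outside the standard range are still returned but flagged in the
#' `extrapolated` attribute.
#'
#' @param a460 Absorbance(s) at 460 nm.
#' @param curve A [fit_standard_curve()] result.
#' @return Halide concentration(s) in mM with a logical attribute
#'   `extrapolated`.
#' @export
halide_from_absorbance <- function(a460, curve) {
  if (!inherits(curve, "standard_curve") || curve$slope <= 0)
    halocat_error("`curve` must be a fitted standard_curve with positive slope",
                  "halocat_invalid_curve")
  conc <- (a460 - curve$intercept) / curve$slope
  structure(conc,
            extrapolated = conc < curve$valid_range[1] |
              conc > curve$valid_range[2])
}

#' Halide-release progress curves from plate readings
#'
#' Maps timed 460 nm readings through the standard curve into halide
#' concentrations, one [progress_curve()] per sample. Duplicate readings at
#' the same (sample, time) are averaged with their SD propagated into the
#' point uncertainty.
#'
#' @param reads Data frame with columns `sample`, `time_s`, `a460`.
#' @param curve A [fit_standard_curve()] result.
#' @param substrate0 Initial substrate concentration (mM).
#' @return Named list of [progress_curve()]s.
#' @export
halide_progress <- function(reads, curve, substrate0) {
  need <- c("sample", "time_s", "a460")
  if (!all(need %in% names(reads)))
    halocat_error("reads must have columns sample, time_s, a460",
                  "halocat_invalid_parameter")
  out <- lapply(split(reads, reads$sample), function(d) {
    conc <- halide_from_absorbance(d$a460, curve)
    agg_m <- tapply(as.numeric(conc), d$time_s, mean)
    agg_s <- tapply(as.numeric(conc), d$time_s, function(x)
      if (length(x) > 1) stats::sd(x) else NA_real_)
    tt <- as.numeric(names(agg_m))
    o <- order(tt)
    progress_curve(tt[o], as.numeric(agg_m)[o],
                   uncertainty = as.numeric(agg_s)[o],
                   substrate0 = substrate0, label = d$sample[1])
  })
  out[order(names(out))]
}
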