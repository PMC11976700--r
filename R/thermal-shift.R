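#' Apparent melting temperature from a thermofluor melt curve
#'
#' Tm is the temperature of the maximal fluorescence change: the curve is
#' smoothed with a centered moving average (window shrinks at the scan
#' edges), differentiated by central finite differences, and the location of
#' the maximal absolute derivative is refined to sub-grid resolution by a
#' quadratic through the peak point and its neighbors. A scan whose
#' derivative peaks at a boundary, or whose transition amplitude is below
#' five times the residual noise estimate (SD of raw minus smoothed), has no
#' usable transition and raises an error.
#'
#' @param curve A [melt_curve()].
#' @param smoothing_window Odd window width (points) for the moving average,
#'   >= 3.
#' @return An object of class `melt_result` with fields `tm` (degrees C),
#'   `method` (`"derivative_max"`), `transition_amplitude`.
#' @export
melting_temperature <- function(curve, smoothing_window = 5) {
  if (smoothing_window < 3 || smoothing_window %% 2 == 0)
    halocat_error("smoothing_window must be odd and >= 3",
                  "halocat_invalid_parameter")
  tt <- curve$temp_c
  ff <- curve$fluorescence
  n <- length(tt)
  half <- (smoothing_window - 1) %/% 2
  if (n < smoothing_window + 4)
    halocat_error("scan too short for the smoothing window",
                  "halocat_invalid_parameter")
  # smooth only where the full window fits; edge-shrunk windows would distort
  # the derivative near the scan boundaries
  valid <- (half + 1):(n - half)
  fs <- vapply(valid, function(i) mean(ff[(i - half):(i + half)]), numeric(1))
  tt <- tt[valid]
  noise <- stats::sd(ff[valid] - fs)
  amplitude <- max(fs) - min(fs)
  if (amplitude <= 5 * noise || amplitude == 0)
    halocat_error("no transition: amplitude not distinguishable from noise",
                  "halocat_no_transition")
  nv <- length(valid)
  interior <- 2:(nv - 1)
  d <- (fs[interior + 1] - fs[interior - 1]) / (tt[interior + 1] - tt[interior - 1])
  k <- which.max(abs(d))
  if (k == 1L || k == length(d))
    halocat_error("derivative maximum at the scan boundary: transition not captured",
                  "halocat_no_transition")
  # quadratic vertex through (T, |dF/dT|) at the peak and its neighbors
  x <- tt[interior][(k - 1):(k + 1)]
  y <- abs(d[(k - 1):(k + 1)])
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  tm <- if (a < 0) -b / (2 * a) else x[2]
  if (tm < x[1] || tm > x[3]) tm <- x[2]
  structure(list(tm = tm, method = "derivative_max",
                 transition_amplitude = amplitude),
            class = "melt_result")
}

#' Melting-temperature shift between a variant and a reference
#'
#' @param curve Variant [melt_curve()].
#' @param reference Reference (e.g. wild-type) [melt_curve()].
#' @param ... Passed to [melting_temperature()].
#' @return List with `tm`, `tm_ref`, `delta_tm` (all degrees C).
#' @export
delta_tm <- function(curve, reference, ...) {
  tmv <- melting_temperature(curve, ...)
  tmr <- melting_temperature(reference, ...)
  list(tm = tmv$tm, tm_ref = tmr$tm, delta_tm = tmv$tm - tmr$tm)
}

#' @export
print.melt_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s, amplitude %.3g)\n",
              x$tm, x$method, x$transition_amplitude))
  invisible(x)
}
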