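#' Enantiomeric ratio from conversion and product ee
#'
#' Closed form for an irreversible kinetic resolution of a racemate:
#' `E = ln[1 - C(1 + ee_P)] / ln[1 - C(1 - ee_P)]`. E is the ratio of the
#' specificity constants of the two enantiomers; it is conversion-invariant
#' for the ideal resolution, which is what makes it the standard selectivity
#' metric.
#'
#' @param conversion Total conversion C, a fraction in (0, 1).
#' @param ee_p Product enantiomeric excess, a fraction in `[0, 1)`.
#' @param preferred Preferred enantiomer label carried into the display
#'   (optional).
#' @return An object of class `e_result` with fields `e_value`, `display`
#'   (two significant figures, ">200" above the display cap), `method`.
#' @export
e_from_c_eep <- function(conversion, ee_p, preferred = NULL) {
  if (!is.numeric(conversion) || conversion <= 0)
    halocat_error(
      "conversion = 0: E is undefined; use the C->0 limit (1+ee_p)/(1-ee_p)",
      "halocat_undefined")
  if (conversion >= 1 || ee_p < 0 || ee_p >= 1)
    halocat_error("need conversion in (0,1) and ee_p in [0,1)",
                  "halocat_domain_error")
  if (conversion * (1 + ee_p) >= 1)
    halocat_error(sprintf(
      "infeasible observation: C(1 + ee_p) = %.3f >= 1 admits no finite E",
      conversion * (1 + ee_p)), "halocat_infeasible_observation")
  e <- log(1 - conversion * (1 + ee_p)) / log(1 - conversion * (1 - ee_p))
  e_result(e, method = "from_c_eep", preferred = preferred)
}

#' Conversion and enantiomeric ratio from substrate and product ee
#'
#' For a two-product resolution the enantiomer mass balance gives
#' `C = ee_S / (ee_S + ee_P)`; E then follows from [e_from_c_eep()]. Not
#' applicable when additional (e.g. regioisomeric) products drain the
#' substrate pool.
#'
#' @param ee_s Remaining-substrate enantiomeric excess (fraction).
#' @param ee_p Product enantiomeric excess (fraction).
#' @param preferred Preferred enantiomer label (optional).
#' @return List with `conversion` and `e_result`.
#' @export
e_from_ees_eep <- function(ee_s, ee_p, preferred = NULL) {
  if (ee_s + ee_p <= 0)
    halocat_error("ee_s = ee_p = 0: conversion and E are undefined",
                  "halocat_undefined")
  conversion <- ee_s / (ee_s + ee_p)
  list(conversion = conversion,
       e_result = e_from_c_eep(conversion, ee_p, preferred = preferred))
}

e_result <- function(e_value, method, display_cap = 200, preferred = NULL) {
  e_value <- max(e_value, 1)
  disp <- if (e_value > display_cap) sprintf(">%g", display_cap)
          else format(signif(e_value, 2))
  if (!is.null(preferred) && nzchar(preferred))
    disp <- sprintf("%s (%s)", disp, preferred)
  structure(list(e_value = e_value, display = disp, method = method),
            class = "e_result")
}

#' @export
print.e_result <- function(x, ...) {
  cat(sprintf("E = %.4g [%s] (%s)\n", x$e_value, x$display, x$method))
  invisible(x)
}

#' Regiochemical product fractions from response-corrected signals
#'
#' Normalizes detector signals (e.g. GC peak areas) for two or more
#' regioisomeric products into fractions, dividing each signal by its
#' response factor first. Missing response factors default to 1 with a
#' warning.
#'
#' @param areas Named numeric vector of signals (>= 2 products, >= 0, not
#'   all zero).
#' @param response_factors Named numeric vector of response factors.
#' @return An object of class `regio_outcome`: named fractions summing to 1.
#' @export
regio_product_fractions <- function(areas, response_factors = NULL) {
  if (length(areas) < 2L)
    halocat_error("need signals for at least two products",
                  "halocat_invalid_parameter")
  if (any(areas < 0))
    halocat_error("signals must be nonnegative", "halocat_invalid_parameter")
  if (all(areas == 0))
    halocat_error("all signals are zero: fractions undefined",
                  "halocat_undefined")
  rf <- rep(1, length(areas)); names(rf) <- names(areas)
  if (!is.null(response_factors)) {
    hit <- names(areas) %in% names(response_factors)
    rf[hit] <- response_factors[names(areas)[hit]]
    if (!all(hit))
      halocat_warn(sprintf("no response factor for: %s; using 1",
                           paste(names(areas)[!hit], collapse = ", ")),
                   "halocat_missing_response_factor")
  }
  corrected <- areas / rf
  structure(corrected / sum(corrected), class = "regio_outcome")
}
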