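#' Rate-versus-concentration dataset
#'
#' Container for the data entering a Michaelis-Menten or Hill fit: one row
#' per measured reaction (replicates appear as repeated concentrations).
#'
#' @param s Varied-species concentrations (mM, >= 0).
#' @param rate Observed rates: per-site rate constants k_obs (1/s) or raw
#'   rates (mM/s), per `normalization`.
#' @param sd Optional per-point SDs (used for inverse-variance weighting).
#' @param normalization `"per_site_rate"` or `"raw_rate"`.
#' @param varied_species Label of the varied species (e.g. "epoxide",
#'   "azide").
#' @return A data frame of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(s, rate, sd = NULL,
                            normalization = c("per_site_rate", "raw_rate"),
                            varied_species = "substrate") {
  normalization <- match.arg(normalization)
  if (any(s < 0)) halocat_error("concentrations must be nonnegative",
                                "halocat_invalid_parameter")
  if (length(s) != length(rate))
    halocat_error("s and rate must have equal length",
                  "halocat_invalid_parameter")
  if (is.null(sd)) sd <- rep(NA_real_, length(s))
  structure(data.frame(s = s, rate = rate, sd = sd),
            normalization = normalization,
            varied_species = as.character(varied_species),
            class = c("kinetic_dataset", "data.frame"))
}

#' Enzyme active-site concentration from a mass loading
#'
#' Converts mg/mL to mM of catalytic sites given the subunit molar mass.
#' Normalization is per subunit by default; pass the oligomer mass divided
#' by sites per oligomer to normalize differently.
#'
#' @param loading_mg_ml Enzyme loading (mg/mL).
#' @param subunit_mass_da Subunit molar mass (Da = g/mol).
#' @return Site concentration in mM.
#' @export
per_site_concentration <- function(loading_mg_ml, subunit_mass_da) {
  stopifnot_number(subunit_mass_da, "subunit_mass_da", 0, Inf, c(FALSE, TRUE))
  loading_mg_ml / subunit_mass_da * 1e3
}

#' Background-subtracted initial rate from a progress curve
#'
#' Fits an ordinary least-squares line (with intercept, so a constant offset
#' in the product values cannot bias the slope) through the early points of
#' the curve: those with conversion at or below `max_conversion`, always
#' keeping at least the three earliest points when available. The blank
#' (no-enzyme negative control) slope is computed identically over the same
#' time window and subtracted; standard errors combine in quadrature.
#'
#' @param curve A [progress_curve()].
#' @param blank Optional background [progress_curve()] to subtract.
#' @param max_conversion Conversion ceiling for the linear window
#'   (default 0.10).
#' @return An object of class `rate_estimate` with fields `v0` (mM/s),
#'   `stderr`, `n_points_used`, `window_end`.
#' @export
initial_rate <- function(curve, blank = NULL, max_conversion = 0.10) {
  s0 <- attr(curve, "substrate0")
  keep <- which(curve$product / s0 <= max_conversion)
  n_min <- min(3L, nrow(curve))
  if (length(keep) < n_min) keep <- seq_len(n_min)
  if (length(keep) < 2L)
    halocat_error("fewer than two usable points in the initial-rate window",
                  "halocat_insufficient_data")
  slope_se <- function(t, p) {
    fit <- stats::lm(p ~ t)
    sm <- quiet_lm_summary(fit)$coefficients
    c(sm["t", "Estimate"], sm["t", "Std. Error"])
  }
  cs <- slope_se(curve$time_s[keep], curve$product[keep])
  if (is.nan(cs[2])) cs[2] <- 0  # perfect 2-point or residual-free fit
  if (!is.null(blank)) {
    bkeep <- which(blank$time_s <= max(curve$time_s[keep]))
    if (length(bkeep) < 2L) bkeep <- seq_len(min(3L, nrow(blank)))
    bs <- slope_se(blank$time_s[bkeep], blank$product[bkeep])
    if (is.nan(bs[2])) bs[2] <- 0
    cs <- c(cs[1] - bs[1], sqrt(cs[2]^2 + bs[2]^2))
  }
  structure(list(v0 = cs[1], stderr = cs[2],
                 n_points_used = length(keep),
                 window_end = max(curve$time_s[keep])),
            class = "rate_estimate")
}

#' Specific activity from an initial rate
#'
#' 1 U = 1 umol/min; with rates in mM/s (= umol/mL/s) and loading in mg/mL,
#' specific activity is `v0 * 60 / loading` U/mg.
#'
#' @param rate A [initial_rate()] result (v0 in mM/s).
#' @param enzyme_loading Enzyme loading (mg/mL, > 0).
#' @return An object of class `specific_activity` with fields `value`, `sd`
#'   (U/mg).
#' @export
specific_activity <- function(rate, enzyme_loading) {
  if (!is.numeric(enzyme_loading) || enzyme_loading <= 0)
    halocat_error("enzyme_loading must be positive",
                  "halocat_invalid_parameter")
  structure(list(value = rate$v0 * 60 / enzyme_loading,
                 sd = rate$stderr * 60 / enzyme_loading),
            class = "specific_activity")
}

# Shared scaffolding for the two saturation fits: weighting, multi-start
# Levenberg-Marquardt with bounds, covariance-based SEs, and delta-method
# SE for the efficiency ratio vmax/K.
fit_saturation <- function(data, formula, starts, lower, upper) {
  args <- list(formula, data = data, lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(
                 maxiter = 500, ftol = 1e-13, ptol = 1e-13))
  if (all(is.finite(data$sd)) && all(data$sd > 0))
    args$weights <- 1 / data$sd^2
  best <- NULL; best_dev <- Inf
  for (st in starts) {
    fit <- tryCatch(
      do.call(minpack.lm::nlsLM, c(args, list(start = st))),
      error = function(e) NULL)
    if (!is.null(fit) && stats::deviance(fit) < best_dev) {
      best <- fit; best_dev <- stats::deviance(fit)
    }
  }
  if (is.null(best))
    halocat_error(sprintf(
      "saturation fit failed to converge from any start (best residual: %s)",
      format(best_dev)), "halocat_fit_failure")
  best
}

efficiency_se <- function(vmax, k, vc) {
  # first-order propagation for vmax/k
  g <- c(1 / k, -vmax / k^2)
  sqrt(drop(t(g) %*% vc %*% g))
}

half_max_conc <- function(s, rate) {
  # concentration at half the maximum observed rate (start value heuristic)
  o <- order(s)
  s <- s[o]; rate <- rate[o]
  target <- max(rate) / 2
  i <- which(rate >= target)[1]
  if (is.na(i) || i == 1L) return(stats::median(s[s > 0]))
  s[i - 1] + (s[i] - s[i - 1]) *
    (target - rate[i - 1]) / (rate[i] - rate[i - 1])
}

#' Fit the Michaelis-Menten rate law
#'
#' Weighted nonlinear least squares for `v = kcat * S / (Km + S)` (with
#' `kcat` read as Vmax when the dataset holds raw rates). Inverse-variance
#' weights are used when per-point SDs are present. Multiple Km starts guard
#' against the shallow likelihood ridge at poorly spanned designs. Standard
#' errors are asymptotic (from the covariance at the optimum); the catalytic
#' efficiency kcat/Km carries a first-order propagated SE.
#'
#' @param data A [kinetic_dataset()] with >= 5 distinct concentrations.
#' @return An object of class `mm_fit` with fields `kcat`, `km`, `se_kcat`,
#'   `se_km`, `efficiency`, `se_efficiency`, and the underlying `fit`.
#' @export
fit_michaelis_menten <- function(data) {
  check_fit_design(data)
  s_half <- half_max_conc(data$s, data$rate)
  vmax0 <- 1.05 * max(data$rate)
  starts <- lapply(c(1, 0.2, 5), function(m)
    list(vmax = vmax0, km = max(s_half * m, 1e-6)))
  fit <- fit_saturation(data, rate ~ vmax * s / (km + s), starts,
                        lower = c(vmax = 0, km = 1e-9),
                        upper = c(vmax = Inf, km = Inf))
  cf <- stats::coef(fit); vc <- stats::vcov(fit)
  if (cf["km"] > max(data$s) || cf["km"] < min(data$s[data$s > 0]))
    halocat_warn("fitted Km lies outside the sampled concentration range",
                 "halocat_poor_design")
  structure(list(kcat = unname(cf["vmax"]), km = unname(cf["km"]),
                 se_kcat = sqrt(vc["vmax", "vmax"]),
                 se_km = sqrt(vc["km", "km"]),
                 efficiency = unname(cf["vmax"] / cf["km"]),
                 se_efficiency = efficiency_se(cf["vmax"], cf["km"], vc),
                 fit = fit),
            class = "mm_fit")
}

#' Fit the Hill rate law
#'
#' Weighted nonlinear least squares for
#' `k_obs = kobs_max * S^n / (K50^n + S^n)` with the Hill coefficient
#' bounded to `[0.3, 10]`. Starts: K50 at the concentration reaching half
#' the maximum observed rate, kobs_max at 1.05x the maximum, with a
#' multi-start over n_H in {1, 2, 4} to escape the correlated n_H/K50
#' ridge. Setting `fix_nh = 1` reduces the model to Michaelis-Menten
#' (nesting).
#'
#' @param data A [kinetic_dataset()] with >= 5 distinct concentrations.
#' @param fix_nh Optional fixed Hill coefficient (drops n_H from the fit).
#' @return An object of class `hill_fit` with fields `kobs_max`, `k50`,
#'   `n_h`, their SEs, `efficiency` (kobs_max/K50) with propagated SE, and
#'   the underlying `fit`.
#' @export
fit_hill <- function(data, fix_nh = NULL) {
  check_fit_design(data)
  s_half <- max(half_max_conc(data$s, data$rate), 1e-6)
  vmax0 <- 1.05 * max(data$rate)
  if (is.null(fix_nh)) {
    starts <- lapply(c(1, 2, 4), function(n0)
      list(kmax = vmax0, k50 = s_half, nh = n0))
    fit <- fit_saturation(data, rate ~ kmax * s^nh / (k50^nh + s^nh), starts,
                          lower = c(kmax = 0, k50 = 1e-9, nh = 0.3),
                          upper = c(kmax = Inf, k50 = Inf, nh = 10))
    cf <- stats::coef(fit); vc <- stats::vcov(fit)
    nh <- unname(cf["nh"]); se_nh <- sqrt(vc["nh", "nh"])
  } else {
    stopifnot_number(fix_nh, "fix_nh", 0.3, 10)
    nh_fixed <- fix_nh
    data$.nh <- nh_fixed
    fit <- fit_saturation(data, rate ~ kmax * s^.nh / (k50^.nh + s^.nh),
                          list(list(kmax = vmax0, k50 = s_half)),
                          lower = c(kmax = 0, k50 = 1e-9),
                          upper = c(kmax = Inf, k50 = Inf))
    cf <- stats::coef(fit); vc <- stats::vcov(fit)
    nh <- nh_fixed; se_nh <- 0
  }
  structure(list(kobs_max = unname(cf["kmax"]), k50 = unname(cf["k50"]),
                 n_h = nh,
                 se_kobs_max = sqrt(vc["kmax", "kmax"]),
                 se_k50 = sqrt(vc["k50", "k50"]), se_n_h = se_nh,
                 efficiency = unname(cf["kmax"] / cf["k50"]),
                 se_efficiency = efficiency_se(cf["kmax"], cf["k50"],
                                               vc[c("kmax", "k50"), c("kmax", "k50")]),
                 fit = fit),
            class = "hill_fit")
}

check_fit_design <- function(data) {
  if (!inherits(data, "kinetic_dataset"))
    halocat_error("`data` must be a kinetic_dataset", "halocat_invalid_parameter")
  if (length(unique(data$s)) < 5L)
    halocat_error("need at least 5 distinct concentrations to fit",
                  "halocat_insufficient_data")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit\n  kcat = %.4g +/- %.2g\n  Km   = %.4g +/- %.2g mM\n  kcat/Km = %.4g +/- %.2g /mM\n",
              x$kcat, x$se_kcat, x$km, x$se_km, x$efficiency, x$se_efficiency))
  invisible(x)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit\n  kobs_max = %.4g +/- %.2g\n  K50      = %.4g +/- %.2g mM\n  n_H      = %.3g +/- %.2g\n  kobs_max/K50 = %.4g +/- %.2g /mM\n",
              x$kobs_max, x$se_kobs_max, x$k50, x$se_k50, x$n_h, x$se_n_h,
              x$efficiency, x$se_efficiency))
  invisible(x)
}
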