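#' True kinetic parameters for simulation
#'
#' Generating truths for synthetic rate data and progress curves. For the
#' hyperbolic (Michaelis-Menten) model `hill_n` is fixed at 1; the Hill model
#' allows cooperativity. `background_rate_constant` is the first-order rate
#' constant of the uncatalyzed chemical reaction (e.g. background azidolysis),
#' which negative-control subtraction must remove downstream.
#'
#' @param model `"michaelis_menten"` or `"hill"`.
#' @param vmax_equivalent Maximal per-enzyme-site rate constant (1/s):
#'   k_cat for the hyperbolic model, k_obs,max for the Hill model.
#' @param half_saturation K_M or K_50 (mM, > 0).
#' @param hill_n Hill coefficient (>= 0.5; forced to 1 for
#'   `michaelis_menten`).
#' @param background_rate_constant Uncatalyzed first-order rate constant
#'   (1/s, >= 0).
#' @return An object of class `true_kinetics`.
#' @export
true_kinetics <- function(model = c("michaelis_menten", "hill"),
                          vmax_equivalent, half_saturation, hill_n = 1,
                          background_rate_constant = 0) {
  model <- match.arg(model)
  stopifnot_number(vmax_equivalent, "vmax_equivalent", 0, Inf)
  stopifnot_number(half_saturation, "half_saturation", 0, Inf, c(FALSE, TRUE))
  stopifnot_number(hill_n, "hill_n", 0.5, Inf)
  stopifnot_number(background_rate_constant, "background_rate_constant", 0, Inf)
  if (model == "michaelis_menten") hill_n <- 1
  structure(list(model = model, vmax_equivalent = vmax_equivalent,
                 half_saturation = half_saturation, hill_n = hill_n,
                 background_rate_constant = background_rate_constant),
            class = "true_kinetics")
}

# Saturation function shared by both rate laws.
rate_law <- function(truth, s) {
  n <- truth$hill_n
  truth$vmax_equivalent * s^n / (truth$half_saturation^n + s^n)
}

#' Simulate the outcome of a kinetic resolution
#'
#' Irreversible two-enantiomer first-order model: starting from a racemate,
#' the fast and slow enantiomers are consumed with rate constants in the
#' ratio `e_true`, so their fractional conversions obey
#' `x_slow = 1 - (1 - x_fast)^(1/E)`. Given a target total conversion
#' C = (x_fast + x_slow)/2 the enantiomer conversions are solved numerically
#' and translated into the observable conversion/ee triple.
#'
#' @param e_true Enantiomeric ratio (>= 1). Values above `e_cap`
#'   (default 1e9, representing E = infinity) are capped.
#' @param target_conversion Total conversion in `[0, 1)`.
#' @param preferred_enantiomer `"S"` or `"R"` (metadata, carried through).
#' @param label Sample label.
#' @param e_cap Cap applied to `e_true`.
#' @return A one-row data frame of class `resolution_observation` with
#'   columns `conversion`, `ee_s`, `ee_p`, `preferred`, `label` (fractions,
#'   not percent).
#' @export
simulate_resolution_outcome <- function(e_true, target_conversion,
                                        preferred_enantiomer = c("S", "R"),
                                        label = "", e_cap = 1e9) {
  preferred_enantiomer <- match.arg(preferred_enantiomer)
  if (!is.numeric(e_true) || length(e_true) != 1L || is.na(e_true) || e_true < 1)
    halocat_error("e_true must be a single number >= 1",
                  "halocat_invalid_parameter")
  stopifnot_number(target_conversion, "target_conversion", 0, 1, c(TRUE, FALSE))
  e <- min(e_true, e_cap)
  cv <- target_conversion
  if (cv == 0) {
    xf <- xs <- 0
  } else if (e == 1) {
    xf <- xs <- cv
  } else {
    # Solve in q = remaining slow-enantiomer fraction: since
    # (1 - x_fast) = (1 - x_slow)^E, conversion fixes q^E + q = 2(1 - C),
    # monotone in q on [0, 1] and numerically stable for extreme E.
    g <- function(q) q^e + q - 2 * (1 - cv)
    q <- stats::uniroot(g, c(0, 1), tol = 1e-15)$root
    xs <- 1 - q
    xf <- 1 - q^e
  }
  denom_s <- (1 - xs) + (1 - xf)
  ee_s <- if (denom_s > 0) (xf - xs) / denom_s else 1
  ee_p <- if (xf + xs > 0) (xf - xs) / (xf + xs) else 0
  structure(data.frame(conversion = cv, ee_s = ee_s, ee_p = ee_p,
                       preferred = preferred_enantiomer,
                       label = as.character(label)),
            class = c("resolution_observation", "data.frame"))
}

#' Simulate a progress curve with chemical background
#'
#' Integrates `dP/dt = [E]_site * vmax * S^n/(K^n + S^n) + k_bg * S` with
#' `S = s0 - P` (substrate depletion; the uncatalyzed background is
#' first-order in substrate). Returns the catalyzed-plus-background curve and
#' the matching background-only (no-enzyme negative control) curve, which
#' downstream initial-rate extraction subtracts.
#'
#' @param truth A [true_kinetics()].
#' @param s0 Initial substrate concentration (mM, > 0).
#' @param enzyme_site_conc Enzyme active-site concentration (mM, >= 0).
#' @param times Sampling times (s), strictly increasing, >= 1 point.
#' @return A list with elements `catalyzed` and `background`, both
#'   [progress_curve()]s.
#' @export
simulate_progress_curve <- function(truth, s0, enzyme_site_conc, times) {
  stopifnot_number(s0, "s0", 0, Inf, c(FALSE, TRUE))
  stopifnot_number(enzyme_site_conc, "enzyme_site_conc", 0, Inf)
  if (length(times) < 1L || any(diff(times) <= 0) || any(times < 0))
    halocat_error("times must be nonnegative and strictly increasing",
                  "halocat_invalid_parameter")
  integrate_p <- function(with_enzyme) {
    deriv <- function(t, y, parms) {
      s <- max(s0 - y[1], 0)
      v_bg <- truth$background_rate_constant * s
      v_cat <- if (with_enzyme) enzyme_site_conc * rate_law(truth, s) else 0
      list(v_cat + v_bg)
    }
    tt <- unique(c(0, times))
    out <- deSolve::lsoda(c(P = 0), tt, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    out[match(times, out[, "time"]), "P"]
  }
  list(catalyzed = progress_curve(times, integrate_p(TRUE),
                                  substrate0 = s0, label = "catalyzed"),
       background = progress_curve(times, integrate_p(FALSE),
                                   substrate0 = s0, label = "background"))
}

#' Simulate two-wavelength plate reads from a progress curve
#'
#' Inverts the quantification chain: for each product concentration the pH
#' that consumes that many protons is solved from the buffer capacity, the
#' indicator deprotonation fraction follows from its equilibrium, and the
#' two absorbances are emitted (additive Gaussian read noise on both
#' channels). A zero-noise trace passed back through
#' [quantify_timeseries()] with the same scenario reproduces the input curve
#' exactly; the curve's first point should carry zero product since the first
#' read is the quantification reference.
#'
#' @param curve A [progress_curve()] (original-sample mM).
#' @param scenario An [assay_scenario()].
#' @param noise_sd Absorbance noise SD (same on both channels).
#' @param seed Integer seed (noise reproducibility); NULL leaves the RNG
#'   state alone.
#' @param a_iso_baseline Noiseless isosbestic absorbance (optical density of
#'   the indicator at the isosbestic point).
#' @param include_minor_terms Passed to [protons_consumed()].
#' @param well_id Well label for the output.
#' @return A [well_timeseries()].
#' @export
simulate_plate_timeseries <- function(curve, scenario, noise_sd = 0,
                                      seed = NULL, a_iso_baseline = 1.0,
                                      include_minor_terms = FALSE,
                                      well_id = "S1") {
  stopifnot_number(noise_sd, "noise_sd", 0, Inf)
  cal <- scenario$calibration
  buf <- scenario$buffer
  dn_mix <- curve$product / scenario$dilution_factor
  ph0 <- buf$initial_ph
  ph <- vapply(seq_along(dn_mix), function(k) {
    d <- dn_mix[k]
    if (d == 0) return(ph0)
    g <- function(p) protons_consumed(ph0, p, buf, cal, include_minor_terms) - d
    if (g(3) * g(11) > 0)
      halocat_error(sprintf(
        "consumed protons exceed buffer capacity at t = %g s",
        curve$time_s[k]), "halocat_range_error")
    stats::uniroot(g, c(3, 11), tol = 1e-13)$root
  }, numeric(1))
  f <- fraction_from_ph(ph, cal)
  bad <- which(f < 0.02 | f > 0.98)
  if (length(bad))
    halocat_error(sprintf(
      "pH excursion leaves the indicator dynamic range (f = %.3f) at t = %g s",
      f[bad[1]], curve$time_s[bad[1]]), "halocat_range_error")
  r <- cal$ratio_acid + f * (cal$ratio_base - cal$ratio_acid)
  if (!is.null(seed)) set.seed(seed)
  n <- length(f)
  noise <- if (noise_sd > 0) matrix(stats::rnorm(2 * n, 0, noise_sd), ncol = 2)
           else matrix(0, n, 2)
  well_timeseries(well_id, curve$time_s,
                  a_report = r * a_iso_baseline + noise[, 1],
                  a_iso = a_iso_baseline + noise[, 2])
}

#' Simulate a rate-versus-concentration kinetic dataset
#'
#' Evaluates the generating rate law on a concentration series and applies
#' multiplicative Gaussian noise (constant coefficient of variation, the
#' simplest model consistent with replicate SDs that scale with the rate).
#'
#' @param truth A [true_kinetics()].
#' @param concentrations Varied-species concentrations (mM).
#' @param replicates Replicate reactions per concentration.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @param varied_species Label of the varied species.
#' @param normalization `"per_site_rate"` (k_obs, 1/s) or `"raw_rate"`.
#' @return A [kinetic_dataset()] with one row per replicate.
#' @export
simulate_rate_dataset <- function(truth, concentrations, replicates = 2,
                                  cv = 0.02, seed = NULL,
                                  varied_species = "substrate",
                                  normalization = "per_site_rate") {
  stopifnot_number(cv, "cv", 0, Inf)
  if (!is.null(seed)) set.seed(seed)
  s <- rep(concentrations, each = replicates)
  mu <- rate_law(truth, s)
  rate <- mu * (1 + if (cv > 0) stats::rnorm(length(s), 0, cv) else 0)
  kinetic_dataset(s = s, rate = rate, normalization = normalization,
                  varied_species = varied_species)
}

#' Ensemble specification for correlated-fluctuation simulation
#'
#' @param mean_coordinates n x 3 matrix of mean residue positions (Angstrom).
#' @param correlation_targets Symmetric positive-semidefinite n x n matrix
#'   with unit diagonal: the inter-residue motion correlations the sampled
#'   ensemble should converge to.
#' @param fluctuation_scale Per-axis displacement SD (Angstrom).
#' @param n_frames Number of frames to sample (>= 2).
#' @param seed Integer seed.
#' @param residue_labels Optional residue labels.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(mean_coordinates, correlation_targets,
                          fluctuation_scale = 1, n_frames = 1000, seed = 1,
                          residue_labels = NULL) {
  mean_coordinates <- as.matrix(mean_coordinates)
  n <- nrow(mean_coordinates)
  ct <- as.matrix(correlation_targets)
  if (ncol(mean_coordinates) != 3L)
    halocat_error("mean_coordinates must be n x 3", "halocat_invalid_parameter")
  if (!isTRUE(all.equal(ct, t(ct), tolerance = 1e-8)) ||
      any(abs(diag(ct) - 1) > 1e-8) || nrow(ct) != n)
    halocat_error("correlation_targets must be symmetric with unit diagonal",
                  "halocat_invalid_parameter")
  if (min(eigen(ct, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    halocat_error("correlation_targets must be positive semidefinite",
                  "halocat_invalid_parameter")
  stopifnot_number(fluctuation_scale, "fluctuation_scale", 0, Inf, c(FALSE, TRUE))
  if (n_frames < 2) halocat_error("n_frames must be >= 2",
                                  "halocat_invalid_parameter")
  if (is.null(residue_labels)) residue_labels <- paste0("R", seq_len(n))
  structure(list(n_residues = n, mean_coordinates = mean_coordinates,
                 correlation_targets = (ct + t(ct)) / 2,
                 fluctuation_scale = fluctuation_scale,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 residue_labels = residue_labels),
            class = "ensemble_spec")
}

#' Coordinate ensemble container
#'
#' @param frames n_frames x n_residues x 3 array of coordinates (Angstrom).
#' @param residue_labels Residue labels (length n_residues).
#' @return An object of class `coordinate_ensemble`.
#' @export
coordinate_ensemble <- function(frames, residue_labels = NULL) {
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    halocat_error("frames must be an n_frames x n_residues x 3 array",
                  "halocat_invalid_parameter")
  if (dim(frames)[1] < 2L)
    halocat_error("need at least two frames", "halocat_invalid_parameter")
  if (!all(is.finite(frames)))
    halocat_error("coordinates must be finite", "halocat_invalid_parameter")
  if (is.null(residue_labels)) residue_labels <- paste0("R", seq_len(dim(frames)[2]))
  structure(list(frames = frames, residue_labels = residue_labels),
            class = "coordinate_ensemble")
}

#' Simulate a coordinate ensemble with prescribed motion correlations
#'
#' Each frame draws one correlated standard-normal vector across residues
#' (via a symmetric square root of the target correlation matrix) and applies
#' the same scalar displacement to x, y and z. This makes the scalar
#' cross-correlation of residue displacements equal the target in
#' expectation, with targets of +/-1 reproduced exactly.
#'
#' @param spec An [ensemble_spec()].
#' @return A [coordinate_ensemble()].
#' @export
simulate_ensemble <- function(spec) {
  if (!inherits(spec, "ensemble_spec"))
    halocat_error("`spec` must be an ensemble_spec", "halocat_invalid_parameter")
  n <- spec$n_residues
  eg <- eigen(spec$correlation_targets, symmetric = TRUE)
  root <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n) %*% t(eg$vectors)
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_frames * n), spec$n_frames, n)
  d <- z %*% root * spec$fluctuation_scale  # frames x residues
  frames <- array(0, c(spec$n_frames, n, 3))
  for (a in 1:3)
    frames[, , a] <- sweep(d, 2, spec$mean_coordinates[, a], `+`)
  coordinate_ensemble(frames, spec$residue_labels)
}

#' Melt-curve container
#'
#' @param temp_c Temperatures (degrees C, strictly increasing, >= 10 points).
#' @param fluorescence Fluorescence readings (a.u.).
#' @param label Curve label.
#' @return A data frame of class `melt_curve`.
#' @export
melt_curve <- function(temp_c, fluorescence, label = "") {
  if (length(temp_c) < 10L)
    halocat_error("need at least 10 temperature points",
                  "halocat_invalid_parameter")
  if (any(diff(temp_c) <= 0))
    halocat_error("temperatures must be strictly increasing",
                  "halocat_invalid_parameter")
  structure(data.frame(temp_c = temp_c, fluorescence = fluorescence),
            label = as.character(label),
            class = c("melt_curve", "data.frame"))
}

#' Simulate a thermofluor melt curve
#'
#' Two-state logistic unfolding reporter:
#' `F(T) = low + (high - low) / (1 + exp((tm - T)/steepness))`, plus
#' additive Gaussian noise.
#'
#' @param tm Midpoint (apparent melting temperature, degrees C).
#' @param steepness Transition width parameter (degrees C, > 0).
#' @param plateaus Numeric `c(low, high)` fluorescence plateaus.
#' @param t_grid Temperature grid (default 10-90 degrees C in 0.5 steps).
#' @param noise_sd Additive fluorescence noise SD.
#' @param seed Integer seed; NULL leaves the RNG state alone.
#' @param label Curve label.
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(tm, steepness, plateaus = c(0, 1),
                                t_grid = seq(10, 90, by = 0.5),
                                noise_sd = 0, seed = NULL, label = "") {
  if (!is.numeric(steepness) || steepness <= 0)
    halocat_error("steepness must be positive", "halocat_invalid_parameter")
  if (length(t_grid) < 10L)
    halocat_error("t_grid needs at least 10 points", "halocat_invalid_parameter")
  if (tm < min(t_grid) || tm > max(t_grid))
    halocat_warn("tm lies outside the temperature grid", "halocat_out_of_range")
  low <- plateaus[1]; high <- plateaus[2]
  f <- low + (high - low) / (1 + exp((tm - t_grid) / steepness))
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  melt_curve(t_grid, f, label = label)
}
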