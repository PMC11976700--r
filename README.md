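# halocat

Quantitative assay analytics for halohydrin dehalogenase (HHDH)
engineering campaigns.

HHDHs open epoxide rings with anionic nucleophiles (azide, nitrite,
cyanide, ...) and dehalogenate vicinal haloalcohols. Characterizing a panel
of engineered variants means quantifying several very different raw
readouts, and halocat implements that whole chain as tested, reusable R
functions:

- **Ratiometric pH-indicator assay** (bromothymol blue): two-wavelength
  plate reads → indicator deprotonation fraction via isosbestic
  normalization → pH (Henderson–Hasselbalch) → consumed protons via buffer
  capacity → product concentration (1 proton per ring-opening event).
- **Halide-release assay**: linear A460 standard curves and their inversion
  into dehalogenation progress curves.
- **Kinetics**: background-subtracted initial rates, specific activities
  (U/mg), and bounded multi-start nonlinear fits of the Michaelis–Menten
  law `v = kcat·S/(Km + S)` and the Hill law
  `k_obs = kobs_max·S^n / (K50^n + S^n)` with asymptotic standard errors
  and propagated catalytic efficiencies.
- **Selectivity**: enantiomeric ratios of kinetic resolutions from the
  closed form `E = ln[1 − C(1+ee_P)] / ln[1 − C(1−ee_P)]`, the
  substrate/product-ee mass-balance route, the field's display conventions
  (2 significant figures, `">200"` cap), and regiochemical product
  fractions.
- **Thermal shift**: apparent melting temperatures as the derivative
  maximum of smoothed thermofluor scans, with sub-grid quadratic
  refinement and ΔTm reporting.
- **Shortest path map (SPM)**: residue-motion cross-correlation and mean
  distance matrices from coordinate ensembles, the `−ln|C|`-weighted
  residue graph (6 Å cutoff), deterministic all-pairs Dijkstra, and
  edge-usage scoring to surface correlated communication pathways.
- **Synthetic data**: seeded generators for every one of these inputs
  (resolutions with a chosen true E, progress curves with chemical
  background, plate reads by inverting the quantification model, logistic
  melt curves, Gaussian ensembles with prescribed correlations), so the
  entire chain is testable without instrument data.

## Worked example

From a resolution observation (46.5% conversion, 82.6% product ee,
S-preference) to its enantiomeric ratio:

```r
library(halocat)
e_from_c_eep(0.465, 0.826, preferred = "S")
#> E = 22.41 [22 (S)] (from_c_eep)
```

A full assay round trip — simulate a cooperative ring-opening reaction
(kobs_max 60.2 /s, K50 14.2 mM, n_H 2.32, 50 nM enzyme sites, 10 mM
substrate), emit noiseless plate reads, and quantify them back:

```r
cal  <- indicator_calibration(pka_apparent = 7.10, ratio_acid = 0.10, ratio_base = 2.00)
scen <- assay_scenario(buffer_spec(1, pka_apparent = 7.20, initial_ph = 7.00),
                       cal, substrate0 = 10)
truth <- true_kinetics("hill", vmax_equivalent = 60.2, half_saturation = 14.2,
                       hill_n = 2.32, background_rate_constant = 2e-5)
sim   <- simulate_progress_curve(truth, s0 = 10, enzyme_site_conc = 5e-5,
                                 times = c(30, 60, 180, 270, 360))
curve <- progress_curve(c(0, sim$catalyzed$time_s), c(0, sim$catalyzed$product),
                        substrate0 = 10)
reads <- simulate_plate_timeseries(curve, scen, well_id = "A1")
quant <- quantify_timeseries(reads, scen)
round(quant$product, 4)
#> [1] 0.0000 0.0336 0.0671 0.1994 0.2968 0.3928
```

The recovered products are the simulated ones (exact to < 1e-9 mM at zero
noise). Rates and a kinetic fit:

```r
blank <- progress_curve(c(0, sim$background$time_s), c(0, sim$background$product),
                        substrate0 = 10)
initial_rate(quant, blank = blank)$v0      # 8.926e-04 mM/s, background-subtracted

d <- simulate_rate_dataset(truth, exp(seq(log(1), log(150), length.out = 12)),
                           replicates = 2, cv = 0.02, seed = 1)
fit_hill(d)
#> Hill fit
#>   kobs_max = 60.47 +/- 0.37
#>   K50      = 14.28 +/- 0.18 mM
#>   n_H      = 2.34 +/- 0.058
#>   kobs_max/K50 = 4.235 +/- 0.043 /mM
```

The fitted parameters recover the generating truth within their standard
errors. A melting temperature from a noisy scan:

```r
melting_temperature(simulate_melt_curve(58.1, 1.5, noise_sd = 0.01, seed = 1))
#> Tm = 58.18 degC (derivative_max, amplitude 1.01)
```

See `vignettes/halocat-methods.Rmd` for the models, assumptions, and
numerical choices behind each stage, and `?run_pipeline` / the
`inst/exec/halocat.R` script for the configurable pipeline and command-line
surface.

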