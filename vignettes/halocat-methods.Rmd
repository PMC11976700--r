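---
title: "Methods: quantitative assay analytics for halohydrin dehalogenase engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative assay analytics for halohydrin dehalogenase engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halocat)
```

halocat implements the analysis chain used in enzyme-engineering campaigns on
halohydrin dehalogenases (HHDHs): enzymes that open epoxide rings with anionic
nucleophiles (azide, nitrite, cyanide, ...) and, in the reverse sense,
dehalogenate vicinal haloalcohols. Each section below states the model behind
one stage, its assumptions, the tunable parameters, and the numerical choices
made where the design was genuinely open.

## 1. Ratiometric pH-indicator quantification

Epoxide ring opening with azide converts a strong acid (HN~3~) into a weak
acid (the azido alcohol), consuming one proton per turnover. In a dilute
buffer the reaction therefore raises the pH, and bromothymol blue (BTB)
reports that rise colorimetrically. The quantification chain inverts this
physics in four steps, each with its own closed form:

1. **Isosbestic normalization.** The reporter/isosbestic absorbance ratio
   `r = A_report / A_iso` is mapped to the indicator's deprotonated fraction
   `f = (r - r_acid) / (r_base - r_acid)`. Because both wavelengths scale
   identically with indicator concentration and optical path length, `f` is
   invariant to dilution, meniscus shape and pipetting volume — the property
   that makes the assay quantitative in plates.
2. **Indicator equilibrium.** `pH = pKa_ind + log10(f / (1 - f))`
   (Henderson–Hasselbalch on the indicator itself).
3. **Buffer capacity.** For a monoprotic buffer at total concentration `B`
   with ionized fraction `alpha(pH) = 1 / (1 + 10^(pKa_buf - pH))`, the
   protons consumed between two pH values are
   `dn = B * (alpha(pH_end) - alpha(pH_start))` (mM). Optional minor terms
   add the indicator's own deprotonation (`~0.03 mM` of indicator) and the
   change in free proton concentration; at a 1–2 mM buffer both are two
   orders of magnitude below the buffer term, so they default to off.
4. **Stoichiometry and dilution.** One proton per ring-opening event, so
   product formed equals protons consumed; the quench (one volume of sample
   into one volume of methanolic indicator) is undone by `dilution_factor`
   (default 2).

**Conventions and degenerate inputs.** All concentrations entering steps
1–3 are expressed in the read mixture; the output product concentration is
on the original-sample scale. The apparent pKa values of indicator
(default 7.10) and buffer (default 7.20, MOPS-like) are *empirical
calibration parameters*: the 50% methanol quench shifts both away from
aqueous literature values, so nothing chemical is hard-coded. `f` is clamped
to `[1e-4, 1 - 1e-4]` with a warning (reads outside the calibrated ratio
span by more than 5% of the span also warn); a clamped extreme read implies
a pH just outside the buffer-capacity domain `[3, 11]` and is pinned to its
boundary. Product values exceeding the nominal substrate concentration are
*flagged, never clamped*, so downstream rate fits see unbiased noise.
Temperature dependence of the apparent pKa values is ignored — calibrate at
assay temperature (documented limitation).

## 2. Halide-release quantification

Dehalogenation is read out through the ferric-thiocyanate halide assay: a
linear standard curve of A460 versus halide concentration (standards spanning
0–3.3 mM) is fitted by ordinary least squares *with* a free intercept — the
reagent blank absorbs measurably and batches differ, so forcing the line
through zero would bias low concentrations. A fit with r² < 0.98 warns.
Readings mapping outside the standard range are returned but flagged as
extrapolated.

## 3. Initial rates, specific activities, and saturation kinetics

**Initial rates.** The linear window takes points with conversion ≤ 10%
(always keeping the three earliest points when available, since sampling
times, not a linearity criterion, are what a plate protocol fixes), fits an
OLS line with intercept — making the slope invariant to constant offsets —
and subtracts the no-enzyme negative-control slope computed over the same
time window. The background subtraction removes the uncatalyzed chemical
reaction (non-negligible for azide at high concentration). Standard errors
combine in quadrature.

**Specific activity.** `U/mg = v0 [mM/s] * 60 / loading [mg/mL]`, using
mM ≡ µmol/mL. Per-site rate constants use
`k_obs = v0 / [E]_site` with `[E]_site` derived from the loading and a
user-supplied subunit molar mass; normalization is per subunit by default
(whether published per-site constants are per subunit or per oligomer is
generally unstated; the choice is configurable and only rescales `k_obs`).

**Model fitting.** Two rate laws are fitted by bounded Levenberg–Marquardt
least squares (`minpack.lm`):

* Michaelis–Menten: `v = kcat * S / (Km + S)` — used for dehalogenation
  kinetics;
* Hill: `k_obs = kobs_max * S^n / (K50^n + S^n)`, `n_H` bounded to
  `[0.3, 10]` — used for epoxide ring opening, where HHDH kinetics are
  sigmoidal (cooperative nucleophile/substrate binding).

Initialization: `K50` (or `Km`) at the concentration reaching half the
maximum observed rate, plateau at 1.05× the maximum; a multi-start over
`n_H ∈ {1, 2, 4}` (for MM, over `Km` scaled by {0.2, 1, 5}) escapes the
shallow correlated ridge between `n_H` and `K50`. Inverse-variance weights
are applied when replicate SDs are present, otherwise the fit is unweighted.
Standard errors are asymptotic (from the covariance at the optimum) and the
catalytic efficiency `kcat/Km` (or `kobs_max/K50`) carries a first-order
propagated SE. Fixing `n_H = 1` reduces the Hill fit to Michaelis–Menten
exactly (model nesting, used as an internal consistency check). Fits that
fail from every start raise an error reporting the best residual rather than
returning a silently bad optimum.

## 4. Enantioselectivity and regioselectivity

For an irreversible kinetic resolution of a racemate, the two enantiomers
are consumed by competing first-order processes whose rate-constant ratio is
the enantiomeric ratio `E`. Their fractional conversions then obey
`x_slow = 1 - (1 - x_fast)^(1/E)`, which gives the classical closed form

```
E = ln[1 - C (1 + ee_P)] / ln[1 - C (1 - ee_P)]
```

with total conversion `C = (x_fast + x_slow)/2` and product enantiomeric
excess `ee_P`. The package also provides the substrate/product-ee route
(`C = ee_S / (ee_S + ee_P)` by mass balance), which is *not* applicable when
regioisomeric side products drain the substrate pool — for regiodivergent
epoxides, compute `E` from the regioisomer-specific conversion and product
ee only. Observations with `C (1 + ee_P) ≥ 1` are geometrically infeasible
under this model and raise an error rather than being clamped.

Display convention: two significant figures, values above 200 rendered
`">200"` (selectivity beyond that is not measurable from ee values near 1),
with the enantiopreference carried as metadata — `"74 (S)"` — never inferred
from the numbers. Note that literature E-values are often computed from
unrounded chromatographic integrals; a printed (C, ee~P~) pair occasionally
implies a slightly different E than the printed one, which is why the closed
form, not any printed value, is the package's ground truth.

Regiochemical product fractions divide each detector signal by its response
factor and normalize; missing response factors default to 1 with a warning.

## 5. Thermal shift (thermofluor) analysis

Apparent melting temperatures are the temperature of maximal fluorescence
change: the scan is smoothed by a centered moving average (default window 5
points at the instrument-typical 0.5 °C step), differentiated by central
differences, and the peak of |dF/dT| is refined to sub-grid resolution with
a quadratic through the peak and its neighbors. Smoothing is restricted to
the region where the full window fits; edge-shrunk windows would distort the
derivative precisely where a spurious boundary maximum must be detected. A
derivative peaking at the scan boundary, or a transition amplitude below 5×
the residual noise (SD of raw minus smoothed), raises a no-transition error.
ΔTm between variant and reference is a first-class output, since stability
engineering is reported as shifts. No two-state thermodynamic (van 't Hoff)
fitting is attempted — the derivative-max criterion is what vendor software
reports, and matching its bit-level smoothing is out of scope.

## 6. Shortest path map (SPM)

From a coordinate ensemble (an MD trajectory, or here a statistical
stand-in) the package computes

* the scalar dynamic cross-correlation matrix
  `C_ij = <dr_i · dr_j> / sqrt(<|dr_i|²> <|dr_j|²>)` of residue reference
  points about their ensemble means, and
* the mean inter-residue distance matrix over frames.

Residue pairs with mean distance < 6 Å and `|C_ij|` ≥ 0.01 are connected
with edge weight `-ln |C_ij|`, so strongly correlated spatial neighbors are
joined by short edges. All-pairs shortest paths are computed by Dijkstra's
algorithm with fully deterministic tie-breaking (the frontier takes the
lowest node index among equal distances; equal-length alternative paths keep
the lowest-index predecessor), and each edge is scored by the number of
unordered residue pairs whose shortest path traverses it. Edges at or above
the 0.8 quantile of positive usages form the map. Numerical notes:

* the logarithm base only rescales all weights uniformly and cannot change
  which paths are shortest — natural log is used;
* `|C| < 0.01` edges are dropped (their weights, ≥ 4.6, would never carry
  paths but would bloat the graph);
* disconnected components are scored per component;
* the map-pruning rule (usage quantile, default 0.8) is an explicit artifact
  decision: published SPM figures do not state their pruning threshold.

The residue reference point is the Cα (or centroid) supplied by the reader;
multi-model PDB input extracts Cα coordinates per model via `bio3d`.

## 7. The synthetic-data generators

Every input the pipeline consumes can be generated with the statistical
structure the analyses assume, which is what makes the full chain testable
without instrument access:

* **Resolutions** follow the two-enantiomer irreversible first-order model
  (no reversibility, no product inhibition — the framework within which the
  closed-form E is exact). Given a true `E` and target conversion, the slow
  enantiomer's remaining fraction `q` solves `q^E + q = 2(1 - C)`
  (monotone on `[0, 1]`, solved by bisection to 1e-15 — stable even at the
  `E = 1e9` cap representing "E = ∞", where the direct `x_fast`
  parametrization underflows).
* **Progress curves** integrate
  `dP/dt = [E]_site · rate_law(S) + k_bg · S` with `S = s0 - P`
  (deSolve/lsoda, rtol 1e-10), returning matched catalyzed and
  background-only curves so negative-control subtraction can be exercised.
* **Plate reads** invert the full quantification chain numerically
  (uniroot on the buffer-capacity relation, tol 1e-13), so the zero-noise
  round trip through `quantify_timeseries()` is exact to well below 1e-9 mM
  with minor terms on or off. Generation fails loudly, naming the timepoint,
  if the requested products would push the indicator outside `f ∈
  [0.02, 0.98]`.
* **Rate datasets** apply multiplicative Gaussian noise at a fixed
  coefficient of variation — the simplest model consistent with replicate
  SDs that scale with the rate; absorbance and fluorescence noise are
  additive Gaussian. Defaults (2% CV on rates, duplicates, 12
  concentrations log-spaced across the design range) mirror a realistic
  plate-kinetics campaign.
* **Ensembles** draw one correlated standard-normal vector per frame from a
  symmetric square root of the target correlation matrix and apply the same
  scalar displacement to x, y and z. This makes the scalar DCCM equal the
  target in expectation and reproduces ±1 targets exactly; the eigenvalue
  square root (rather than Cholesky) tolerates the rank-deficient targets
  that ±1 entries create.
* **Melt curves** are two-state logistics
  `F(T) = low + (high - low)/(1 + exp((tm - T)/steepness))` plus additive
  noise on the instrument-typical 10–90 °C, 0.5 °C grid.

All generators are deterministic given their seed.

**What the generators do not emulate** — and hence what passing tests do
*not* show about real data: pipetting outliers and plate edge effects,
instrument drift within a scan, substrate evaporation, enzyme inactivation
during the assay, deviations from two-state unfolding, product inhibition in
resolutions, and the non-Gaussian, anisotropic fluctuations of real MD
trajectories. The ensemble generator in particular reproduces prescribed
*pairwise scalar* correlations, not realistic protein mechanics.

## 8. Verification problem sizes

The test suite checks the round-trip laws (generator ∘ quantifier =
identity at zero noise, resolution → E recovery to 1e-6 relative for E up
to 500), oracle equivalence of Dijkstra against brute-force simple-path
enumeration on ~100 random graphs of up to 8 nodes, planted-pathway
recovery in ensembles of 13 residues × 1500 frames across 10 seeds,
Tm recovery within 0.5 °C on 200 noisy scans, and kinetic parameter
recovery over ~200 seeded replicate fits at 2% CV across cooperativity
levels `n_H` = 1.14–4.58. These sizes were chosen to make sampling
variability, not luck, the deciding factor while keeping the default test
run fast on a laptop.

## 9. Known limitations

* The quantification chain assumes a monoprotic buffer and 1:1 proton
  stoichiometry; polyprotic buffers or substrates would need a different
  capacity term.
* Fit uncertainties are asymptotic; for strongly correlated `n_H`/`K50`
  posteriors a profile or bootstrap interval would be wider.
* The SPM stand-in ensembles validate the graph machinery, not any claim
  about real allosteric pathways.
* Reported per-site rate constants depend on the subunit-mass normalization
  choice documented above.
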