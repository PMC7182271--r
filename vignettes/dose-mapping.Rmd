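---
title: "Iterative geostatistical dose mapping: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative geostatistical dose mapping: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a large-scale radiological release, every exposed person cannot be
dose-assessed individually: dosimetry and biodosimetry throughput are orders
of magnitude below the demand, and every field excursion exposes responders.
`radkrige` implements a triage-mapping protocol that reconstructs the spatial
dose distribution — in particular the territory where absorbed dose reaches
the 2 Gy treatment-eligibility threshold for Acute Radiation Syndrome — from
measurements at a small, adaptively chosen fraction of locations.

The protocol is iterative:

1. **Initial sampling.** Random locations are drawn in each census-like
   subdivision overlapping or immediately surrounding the suspected plume,
   in numbers proportional to subdivision population (default 0.1%).
   Unirradiated (0 Gy) locations in the surrounding subdivisions are kept:
   they anchor the interpolation boundary. Restricting them to the immediate
   surroundings matters, because a large excess of zeros depresses the
   interpolated plume's range.
2. **Kriging.** A dose surface with prediction standard errors is estimated
   on an analysis grid from all measurements so far.
3. **Densification.** Up to 200 new sampling locations are chosen among grid
   cells whose upper-quartile predicted dose reaches the 2 Gy threshold,
   ranked by prediction standard error — i.e. where the map is least certain
   among regions that plausibly matter for triage.
4. **Convergence testing.** The dose-band structure of consecutive surfaces
   is compared through an 8-band overlap heat matrix; sampling stops when
   consecutive maps agree to the chosen stringency, when densification finds
   no new locations, or at an iteration cap.

## Dose bands and the stopping metrics

Surfaces are summarized by eight dose bands: `<1, 1–2, 2–3, 3–4, 4–5, 5–6,
6–7, >7` Gy (half-open intervals, first band strictly positive). For two
consecutive plumes the overlap matrix entry $(i,j)$ is the symmetric mean of
area ratios

$$ M_{ij} = \tfrac12\left(\frac{|C_i \cap P_j|}{|C_i|} +
                          \frac{|C_i \cap P_j|}{|P_j|}\right), $$

so identical plumes produce the identity matrix. Only the diagonal
$A_i = M_{ii}$ enters the two stopping statistics,

$$ \mathrm{BCD} = \frac{\sum_{i=1}^{8} |1 - A_i|}{\sum_{i=1}^{8} (1 + A_i)},
   \qquad
   \mathrm{RMSD} = \sqrt{\tfrac18 \sum_{i=1}^{8} (1 - A_i)^2}. $$

A uniform diagonal $a$ gives the closed forms $\mathrm{BCD} = (1-a)/(1+a)$
and $\mathrm{RMSD} = 1-a$; at the default 90% stringency the thresholds are
therefore exactly $1/19$ and $0.1$, and at 99% they are $1/199$ and $0.01$.
Iteration stops when **either** metric drops strictly below its threshold
("dropped below" is read as strict inequality; sitting exactly on the
threshold continues).

Two conventions the formulas do not fix:

* a diagonal cell whose band is empty in **both** plumes counts as overlap 1
  (no disagreement — outer bands routinely vanish in weak plumes); empty on
  one side only counts as 0;
* the symmetric mean-of-ratios above is one of several "average overlap"
  definitions that satisfy the identity-matrix property (Dice overlap is
  another); the choice is fixed here and unit-tested against that property.

## The synthetic scenario generator

No transport model is bundled. Ground truth is an analytic, star-shaped
"teardrop" dose field
$D(r,\theta) = A\exp\{-(r/R(\theta))^2\}$ about the epicenter, where the
directional radius $R(\theta)$ equals the configured downwind length along
the wind bearing, half the crosswind width perpendicular to it, and is
modulated by seeded low-order harmonics so replicate plumes are irregular.
Star-shapedness guarantees every level set is a single simple closed curve
and that rings nest strictly — the two properties downstream code relies on.
Contours are extracted analytically every 0.5 Gy from 0.5 Gy up to the peak
(default 8 Gy, 16 levels) and resampled to equal arc-length spacing
(default 250 vertices per ring, ~4000 boundary points per plume). True dose
at a query point is the **outer-boundary assignment**: the highest contour
level whose ring contains the point, 0 outside all rings. This deliberately
reproduces the protocol's documented systematic error — locations between
contours are credited with the outer contour's dose rather than an
interpolated value.

Weather variants are fixed multiplicative shape factors (rain: 0.70 × length,
0.85 × width; snow: 0.60 × length, 0.80 × width), standing in for
precipitation scavenging; only a morphology perturbation is needed since the
protocol itself is weather-agnostic.

The population map is a seeded, jittered rectangular tessellation with
uniform within-subdivision density. Density regimes straddle the
urban/rural classification boundary of 10,000 persons per square mile
(3861 /km²): urban draws 4000–9000 /km², rural 20–1500 /km². Populations are
allocated with largest-remainder rounding so configured totals are conserved
exactly.

**Reference scenario.** The default configuration uses a 30 × 30 km region,
36 subdivisions, and an 8 × 2 km plume peaking at 8 Gy. The footprint was
sized so that 0.1% population sampling yields irradiated sample totals in
the low hundreds — the operating regime in which the protocol is meant to
work (initial irradiated counts of order 10²,  converged totals of a few
hundred). What the generator deliberately does **not** emulate: transport
physics (deposition, decay, terrain), time-dependent plumes, infrastructure
shielding, non-uniform within-subdivision population, multi-part contours.
Passing tests therefore demonstrate correctness of the *protocol* under a
clean dispersion geometry, not fidelity to any real release.

## Kriging engines

Ordinary, simple and universal kriging solve the standard (augmented)
covariance systems per grid cell; the solver is compiled (RcppArmadillo).
Conventions and numerical choices:

* Semivariogram families: exponential (default), spherical, gaussian, as
  `γ(h) = nugget + psill·(1 − ρ(h/range))`; the exponential/gaussian `range`
  is the scale parameter, not the effective range.
* Default fitting is pair-count-weighted least squares on the binned
  empirical semivariogram (15 equal-width bins to half the maximum lag).
  Optimizer failure falls back, with a warning, to nugget 0, sill = mean
  empirical semivariance, range = half max lag. A restricted
  maximum-likelihood fitter (constant mean, profile-free parameterisation,
  Nelder–Mead on log parameters) backs the EBK ensemble.
* The covariance at zero lag includes the nugget, so zero-nugget models
  interpolate exactly (prediction = measurement, SE = 0 at sampled cells).
* Effectively coincident coordinates are averaged before solving (they make
  the system singular). Note the *candidate* dedup rule is coarser — one
  grid cell — and lives in the densification step where repeat dispatches
  are the concern.
* Predictions are clamped at 0 Gy post hoc (dose is physical; the raw
  surface is kept alongside for diagnostics).
* Up to 500 samples the system is solved globally (one factorization, all
  cells); beyond that each cell uses its 64 nearest samples. The default
  analysis grid is 200 × 200 cells over the boundary-subdivision bounding
  box plus a 10% margin.

**Empirical Bayesian kriging** is approximated, not re-derived from any
proprietary implementation: samples are partitioned into local subsets
(k-means, default 10), a base model is REML-fitted per subset, and the
semivariogram ensemble is the base model plus `n_sims − 1` models refitted
to Gaussian data simulated from it at the subset's locations (default
ensemble size 30). Cells are predicted by the nearest subset's ensemble as
an equal-weight mixture of per-model ordinary-kriging predictions; the
mixture variance adds the between-model spread of predictions to the mean
within-model kriging variance, which is how measurement/model uncertainty
propagates into the standard errors. Defining the ensemble to contain the
base REML model makes the degenerate case exact: one subset, one simulation
*is* ordinary kriging under the REML fit.

The scenario orchestrator defaults to ordinary kriging: on the analytic
teardrop fields the four variants recover similar ≥2 Gy bands (the method
comparison helper reports per-variant overlap), and ordinary keeps replicate
ensembles fast. EBK remains one configuration switch away, with the caveat
that its ensemble multiplies kriging cost roughly by `n_sims`.

## Densification details

`QUARTILE_THRESHOLD_UPPER` is interpreted as the Gaussian upper quartile of
the prediction distribution: a cell is eligible when
`prediction + 0.6745 · SE ≥ threshold` (0.6745 being the 75th-percentile
normal deviate). Eligible cells are ranked by descending SE with ties broken
by (row, column) index, and accepted greedily under a minimum spacing of one
grid cell — without spacing the top of the ranking is a cluster of adjacent
cells that are nearly redundant once one of them is measured. Candidates
falling in a cell already holding a sample are skipped entirely (the
original tooling would sometimes re-emit a previously sampled coordinate;
this implementation forbids repeats, which can only reduce sample counts).
The excluded "0 Gy envelope" is the union of subdivisions whose every sample
so far measured 0 Gy and whose polygon does not touch the current positive
region — locations there need not be resampled. A manual-candidate hook
(CSV of coordinates) supports supervised repair of under-covered regions.

## Accuracy scoring

Ground truth must be compared in the derived plume's own representation, so
the contour vertices (each valued at its level) are kriged onto the shared
grid with a zero-nugget model — an exact interpolator of the vertices. The
vertex set is extended with a 0 Gy envelope ring (the outermost contour
extrapolated outward by the spacing of the two lowest contours): the contour
family conceptually spans the dose range down to 0, and without the zero
ring ordinary kriging would extrapolate positive dose arbitrarily far from
the plume. With it, the truth surface agrees with the outer-boundary dose
query within one contour step (0.5 Gy) at ≥95% of analysis-grid cells.

Region populations use the uniform-density-within-subdivision rule:
`pop(region) = Σ_s area(region ∩ s) · population(s) / area(s)`, computed
exactly (rectangle clipping) per grid cell, so the whole-map population is
conserved to floating point. Reported per threshold (2 and 3 Gy):
**recall**, the percentage of the true at-threshold population whose
territory the derived plume captures, and the **false-positive fraction**,
the percentage of the derived at-threshold population that is truly below
threshold.

## Orchestration, seeds and problem sizes

An iteration is one kriging pass; the initial kriging is iteration 1 (so
reported counts are comparable with convergence at iteration `k` meaning
`k − 1` densification rounds). Each replicate derives named substream seeds
(sampling, error, EBK, densification) arithmetically from its single seed,
so perturbation arms reuse identical sampling draws and whole runs are pure
functions of configuration plus seed. Failure is a status, not an error: a
replicate with zero irradiated initial samples, or whose first surface has
no positive region, reports `failed_no_plume` — the documented failure mode
of sparse low-density scenarios, which larger sampling fractions (0.2%, 1%)
repair. The iteration cap defaults to 15, comfortably above the 3–10
typically needed at 90% stringency; the 99% mode takes a few more.

Problem sizes in the shipped tests: the test suite exercises the reference
scenario on 150-cell (acceptance ensembles) and 60-cell (fast protocol
tests) analysis grids rather than the 200-cell default. At 150 cells the
protocol behavior — iteration counts, densification volumes, accuracy — is
indistinguishable from 200; coarser grids shrink densification rounds
(spacing is in cell units) and make convergence trivially fast, which is why
the fast tests assert protocol *contracts* rather than iteration counts.

## Known limitations

* Planar kilometre coordinates throughout; the equirectangular import shim
  is adequate at city scale only.
* Simple kriging with the default constant mean is expected to struggle on
  strongly trended dose fields (it may fail to produce a contiguous plume —
  an observed property of the method, not a defect of the implementation).
* The EBK approximation is declared as such; subset size, overlap and priors
  of proprietary implementations are not reproduced.
* Multi-part (non-simply-connected) ground-truth contours are unsupported
  input.
* Population is static; no diurnal shifts, sheltering or cumulative-dose
  dynamics.
* Measured doses take values exactly at the half-Gy contour levels, half of
  which coincide with the integer band edges used by the overlap metrics.
  Near-plateau regions of a kriged surface can therefore flip between
  adjacent bands under the small per-iteration semivariogram refits, which
  holds the overlap diagonal just below target in hard runs (notably under
  directionally biased sampling, where the under-sampled plume core
  amplifies the effect). Such runs end through the candidate-exhaustion
  stop — the documented premature-stabilization mode — rather than the
  metric rule. This sensitivity is inherent to the band/level definitions,
  not a numerical defect, and is worth knowing when interpreting stalled
  convergence traces.
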