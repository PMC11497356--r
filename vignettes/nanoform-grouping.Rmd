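---
title: "Dissolution-driven grouping of soluble metallic nanoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissolution-driven grouping of soluble metallic nanoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotoxkin)
```

## The model and its assumptions

`nanotoxkin` treats a suspension of soluble metallic nanoparticles as a
two-stressor mixture whose composition changes through time as the
particles dissolve. The model rests on a compact set of assumptions:

* particles are monodisperse spheres that stay spherical while
  dissolving, shrinking continuously from the surface;
* the dissolution rate constant k (mass shed per unit surface area per
  unit time) is a material property, independent of particle size;
* at t = 0 the suspension contains no ions; total metal mass is
  conserved, so the ion concentration is the complement of the particle
  concentration;
* the suspension is homogeneous: aggregation, sedimentation and other
  fate processes are not modelled;
* ions and particles act through different modes of toxic action, so
  their Hill effects combine by response addition;
* Hill coefficients do not change with exposure duration;
* particles are at most 5 times less toxic than the ions
  (EC50_NF between 1 and 5 EC50_ion), and test doses span 0.1 to 5
  times the particle EC50;
* 10% and 90% ion contribution are the grouping cutoffs (configurable;
  the values are conventions, not biology).

Under surface-limited loss the diameter shrinks linearly,
D(t) = D₀(1 − Pt) with P = 2k/(ρD₀), the particle mass concentration
follows the cube law C_NF(t) = C₀(1 − Pt)³, and ions take up the
remainder. Pt is the natural dimensionless clock: Pt = 1 is complete
dissolution, and every grouping statement in the package is a statement
about Pt first and about (k, t, D₀, ρ) only through the identity
Pt = 2kt/(ρD₀).

A finite test volume would in reality approach a saturation steady
state as released ions suppress further dissolution. The implemented
kinetics dissolve to 100%, which is the stated model; no solubility cap
is added, and predictions close to complete dissolution should be read
with that in mind.

## From concentrations to the ion contribution

Both stressors follow Hill concentration–response curves
E(c) = c^η/(c^η + EC50^η). Because the modes of action differ, the
suspension effect is E_tox = 1 − (1 − E_ion)(1 − E_NF), and the ion
contribution is Contr_ion = E_ion/E_tox, defined as 0 when E_tox = 0
(no dissolution, sub-threshold dose) to avoid 0/0. Scaling
concentrations by the two EC50s collapses the pipeline to five
dimensionless quantities: A = C₀/EC50_NF, B = C₀/EC50_ion, the progress
τ = Pt, and the Hill coefficients η₁ (ions) and η₂ (particles). The
convention that B/A equals the EC50 ratio EC50_NF/EC50_ion lives in one
constructor (`dimensionless_state()`); with it, the toxicity-ratio
assumption reads A ≤ B ≤ 5A. `suspension_effect_timecourse()` runs the
dimensional pipeline and agrees with the dimensionless kernel to
numerical identity, which the test suite checks on randomized draws.

Contr_ion is monotone: non-decreasing in τ (ions accumulate, particles
deplete), non-decreasing in B and non-increasing in A. These
monotonicities are what make the boundary analysis well-posed.

## Regime boundaries and their numerics

For a whole assumption region of (A, B) values, the running minimum and
maximum of Contr_ion over the region are themselves non-decreasing
functions of τ rising from 0 to 1. Four τ crossings therefore structure
the classification: where the maximum passes the low cutoff (below
this, particle-dominated everywhere), where the minimum passes the low
cutoff, where the maximum passes the high cutoff, and where the minimum
passes the high cutoff (above this, ion-dominated everywhere). The
order of the two intermediate crossings decides whether a band exists
in which all three classes are possible; steep particle curves
(η₂ ≫ η₁) produce one, the symmetric η₁ = η₂ = 1 scenario does not.

Numerical choices, all configurable:

* **Extrema search** (`contr_extrema()`): log-spaced grid over dose A
  and EC50 ratio r (default 201 × 201), then golden-section refinement
  (`stats::optimize`, tolerance 1e-10 in log coordinates) along each
  coordinate around the best cell. Monotonicity places the true extrema
  on the region boundary, so the coarse grid cannot trap the refinement
  in a spurious interior cell; a dense brute-force grid oracle in the
  test suite confirms agreement to 5e-3.
* **Crossing location** (`find_pt_boundaries()`): `stats::uniroot`
  bisection on τ ∈ (0, 1), default tolerance 1e-6. Degenerate
  single-point regions are allowed and are how the two analytically
  solvable anchors are checked (at A = B = 1, η = 1 the 90% crossing
  solves f² + 9f − 1 = 0 with f = (1 − τ)³, giving τ = 0.5212; the
  corner A = 10, B = 50 gives the 10% crossing at τ = 0.00067).
* **Ties**: a τ exactly on a pure-band boundary classifies into the
  pure class, an arbitrary but documented convention.
* **Clipping**: at and beyond complete dissolution all particle
  quantities are exactly zero, never small negatives, including when
  the time is computed as 1/P in floating point.
* **Hill powers** are evaluated in log space (`plogis(η log x)`), so
  extreme Hill coefficients or extreme doses neither overflow nor
  underflow.

The published boundary constants for the three standard scenarios —
(η₁, η₂) = (1, 1): 0.00067/0.0295/0.103/0.521; (1, 5):
0.000012/0.00095/0.022/0.465; (4, 8): 0.0074/0.02/0.124/0.26 — are
shipped as reference presets (`reference_thresholds()`) and are the
defaults used by the grouping layer. They are deliberately *data*, not
engine output: the exact search region behind them is not fully
determined by their published description (with the literal default
region the engine's (1, 1) upper boundary lands near 0.53 rather than
0.521, consistent with extrema attained at specific boundary points
such as A = B = 1). The engine (`find_pt_boundaries()`) recomputes
boundaries from first principles for any region the user specifies;
the presets reproduce the published decision rules. The two are kept
separate on purpose, and neither is adjusted to match the other.

## Grouping and critical values

`classify_nanoform()` computes Pt and maps it through the regime bands.
In bands where several outcomes remain possible the result is
`indeterminate` unless the two EC50s are supplied, in which case the
pointwise Contr_ion decides with strict cutoff inequalities.
`critical_k()`, `critical_t()`, `critical_diameter()` and
`critical_density()` are the algebraic inversions of Pt = 2kt/(ρD₀);
`generate_table()` assembles the silver/copper screening tables
(critical k rounded to two decimals, four below 0.01 ng/cm²/h where
rates may not be experimentally determinable). The copper table is
reproduced within 0.5% rather than exactly: the published copper rows
are internally consistent with a density of about 8.94 g/cm³ while the
stated (and shipped) preset is 8.95 g/cm³, and the preset is not
silently changed.

## Synthetic fixtures

`generate_fixture_specs()` draws reproducible nanoform batches for
testing and screening demonstrations: k log-uniform over 1e-4 to 1e3
ng/cm²/h (spanning effectively insoluble coatings to fast-dissolving
bare metal), diameters log-uniform over 5–200 nm (the common nanoform
range), silver or copper densities, and total concentrations
log-uniform over 1e-4 to 1e-1 g/L, the span of typical aquatic test
doses. These fixtures emulate the *parameter* diversity of real
batches, not real data: they are monodisperse, perfectly spherical,
aggregation-free suspensions by construction. Passing tests therefore
demonstrate the internal correctness of the kinetics, mixture algebra
and boundary search — not that any real suspension obeys the
assumptions. Size distributions, aggregation/sedimentation, platelet
morphologies, medium-dependence of k (e.g. pH) and estimation of Hill
parameters from experimental dose–response data are out of scope.

## Problem sizes used in the checks

The shipped tests run the boundary search with grid resolutions of
31–61 points per axis against brute-force oracle grids of 50–400
points per axis, property checks on 20–1000 randomized parameter draws
under fixed seeds, and a forward-Euler dissolution oracle at 1e4 steps
per dissolution time. These sizes were chosen so the full suite
exercises every code path at tolerances well inside the engine's
refinement accuracy.
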