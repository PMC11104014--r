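---
title: "Encounter-rate scaling of phage virions with motionless bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter-rate scaling of phage virions with motionless bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phagewalk)
```

## The model

A phage virion searching for a bacterium by diffusion is modelled as the
simplest Markov process that still captures the geometry: a point walker
on the integer lattice `[0, L-1]^3` that moves exactly one unit per step
in one of at most six directions, chosen uniformly at random. A
motionless spherical bacterium of radius `R` sits at the cube centre
`((L-1)/2, (L-1)/2, (L-1)/2)`; after every move the squared Euclidean
distance to the centre is compared with `R^2`, and the walk terminates at
the first strict crossing `D < R`. The number of prior steps is the
outcome of one "technical repeat"; the simulation output is the mean over
many repeats.

The assumptions this encodes:

* **The bacterium is motionless.** Only the virion diffuses. This is the
  classical setting in which the diffusion-limited rate constant
  `k = 4*pi*R*C*f` was derived; bacterial motility would add a relative
  diffusivity and is deliberately outside this model.
* **The virion is a point.** Bacteria are typically an order of magnitude
  larger than virions, so the target radius alone sets the encounter
  geometry; no excluded volume is modelled at contact.
* **Absorbing target.** Every encounter ends the search; the attachment
  probability `f` enters only the closed-form calculators, not the walk.
* **Reflecting-by-restriction walls.** At a face, edge or corner of the
  cube the move is drawn uniformly from the feasible 5, 4 or 3 moves.

The scientific question is how the mean number of steps to encounter
scales with `R`: as `1/R` (diffusion-limited theory) or as `1/R^2`
(collisional cross-section intuition). The package measures this without
assuming either answer, then compares both.

## The estimator

Each independent run produces a relative curve: mean steps at each radius
expressed as a percentage of the mean at the reference radius
(`100 * mean(R)/mean(R_ref)`, exactly 100 at the reference). The
candidate laws give predicted curves `100 * (R_ref/R)^p` for `p = 1, 2`.
Per run, an ordinary least-squares line of simulated percentage (y) on
predicted percentage (x) yields slope `m`, intercept `b` and Pearson
correlation `r`; a correct law should give `m` near 1, `b` near 0 and `r`
near 1. Across runs, `encounter_fit()`/`comparison_table()` report column
means, n−1 standard deviations, and two-tailed t-test p-values comparing
each statistic between the two exponents. Summary rows are always
recomputed from the per-run rows, never cached.

The t-test variant is the unpaired unequal-variance (Welch) test with
Welch–Satterthwaite degrees of freedom. This choice is pinned by
verification: applied to the twenty published per-run rows shipped in
`inst/extdata/tables_fixture.csv`, Welch reproduces every published
p-value to its printed precision (0.0168 and 0.0004 for the wide-radius
table's slope and correlation columns, 0.0017 for the narrow-radius
table's correlation column), whereas pooled-variance and paired variants
do not. Both alternatives remain available via the `variant`/`t_variant`
arguments. No multiple-testing correction is applied, matching the
tables being reproduced. "0.0000" cells in those tables are treated as
bounds (`< 1e-4`), not as exact zeros.

## Parameters that matter

* `edge_length` (`L`, lattice units): the diffusion volume. Study-scale
  values are 500–10000; the desk-scale analyses here use 500 (with radii
  up to 30) so that `R/L <= 0.06`.
* `target_radius` (`R`, lattice units): one lattice unit is one
  virion diameter. Curves are anchored at `R = 10` because for smaller
  radii the discrete grid resolves the sphere poorly: the strict `D < R`
  rule on integer positions distorts the effective capture radius when
  `R` is of order 1.
* `repeats`: technical repeats per radius; 100–200 at study scale. Mean
  first-passage times from a distant start are approximately
  exponentially distributed (SD ≈ mean), so the relative standard error
  of a per-radius mean is about `1/sqrt(repeats)`.
* `reference_radius` (default 10): the self-normalization anchor. Each
  run is normalized to its own reference batch, so runs remain mutually
  independent.
* `start_mode`: `"corner"` (default; all corners are equivalent by
  symmetry) or `"random_interior"` (uniform over lattice points, redrawn
  until outside the sphere — so recorded walks always take at least one
  step).
* `max_steps` (default `1e10`): a cap that converts a mis-configured
  endless walk into an explicit `cap_exceeded` outcome. Capped walks are
  counted per radius (`n_capped`) and downstream analysis refuses to
  normalize them unless forced.
* `boundary_policy`: `"reflect"` (default) draws uniformly from the
  feasible moves, so blocked directions are never spent as steps;
  `"stay"` draws from all six and spends a step in place on a blocked
  draw. The wall rule is under-determined by a verbal description of
  "movement limited to steps that retain the phage inside"; both
  readings are implemented because they differ in boundary dwell time
  (the exact solver confirms strictly longer corner-start first passage
  under `"stay"`). All headline analyses use `"reflect"`.

## Numerical choices

* **Distance comparisons are exact.** Positions are integers and the
  centre is a half-integer for even `L`, so the walk compares
  `4*D^2` (an integer) with `(2R)^2`; a point at exactly distance `R`
  has *not* encountered, and no square roots are taken in the hot loop.
* **Seeding.** One master seed; each walk's xoshiro256++ stream is keyed
  by `splitmix64(master, run_index, radius_index, repeat_index)`.
  Repeats are therefore independent, reproducible regardless of
  execution order, and extending a radius schedule never perturbs
  existing streams. Direction draws use Lemire's bounded-multiply
  reduction.
* **Exact oracle.** `fp_mean_exact()` solves `tau = 1 + P tau` over the
  non-absorbing states with a sparse LU (`Matrix`), giving the exact
  expected step count from the corner (or averaged over all transient
  states for random starts). It enumerates all `L^3` states and is
  guarded at `L <= 25`. Degenerate geometries — no absorbing lattice
  point, or every point absorbing — are refused with explicit errors.
* **Dispersion.** Per-radius standard deviations use the n−1
  denominator; a single-repeat experiment reports `sd = 0` and carries a
  degenerate-sample flag.
* **Zero-variance t-tests** return `p = 1` for identical samples and the
  limiting `p = 0` (with a warning) for unequal constant samples.

## What the tests do and do not establish

The validation ladder is: (i) the encounter region matches exhaustive
enumeration of all lattice points; (ii) Monte Carlo means match the
exact linear-solve oracle within 3 standard errors for every lattice up
to `L = 9` (and at `L = 25`); (iii) at `L = 300`, doubling `R` from 10
to 20 halves the mean steps within Monte Carlo error; (iv) at `L = 500`,
radii 10–30, the regression against `1/R^1` recovers slope ≈ 1 and beats
`1/R^2` on correlation. Scale choices in (iii)–(iv) are deliberate: the
`1/R` law is an asymptotic statement for `1 << R << L`. When `R/L`
grows beyond roughly a tenth, confinement makes large targets
disproportionately fast to find (the published wide-radius sweeps show
the same drift below the `1/R` prediction at their largest radii); when
`R` approaches one lattice unit, discreteness dominates instead.

The full study-scale sweeps — radii to 1000 inside cubes of 2500–10000
units, with mean walk lengths of order `1e8`–`1e9` steps — are
reproduced in shape but not re-run here; the desk-scale protocol (cube
500, radii 10–30 step 1, 20 repeats, 3 runs, as in
`scripts/acceptance.R`) completes in minutes on one CPU. One property of
that reduced protocol deserves note: because each run is normalized by
its own noisy reference mean (relative SE ≈ 22% at 20 repeats), the
fitted slope acquires a Jensen-type upward bias and substantial run-run
spread; both shrink like `1/repeats` and are negligible at the study's
200 repeats. The reduced protocol therefore brackets, rather than
pinpoints, the published slope values.

## Synthetic data

Two seeded generators stand in for data the analysis consumes but that
cannot be shipped:

* `size_rate_sqrt` emulates adsorption-rate measurements against cell
  surface area across growth conditions, with
  `rate = 0.03 * sqrt(size) + N(0, 0.005)` over a roughly four-fold
  range of the size measure — i.e. data generated under the
  radius-linear law with measurement noise, at a slope and noise level
  matching normalized adsorption-rate units. The square-root re-analysis
  (`reanalyze_size_vs_rate()`) should, and on average does, give the
  higher correlation to the `sqrt(size)` predictor on these data. Real
  measurements of this kind differ in ways the generator does not
  emulate: sizes cluster irregularly rather than spreading evenly,
  noise is likely heteroscedastic, and the size range is narrow enough
  that both predictors correlate highly — so passing tests show the
  machinery discriminates the laws it was built to discriminate, not
  that any particular experimental dataset does.
* `decay_curve` produces free-phage decay `P0 * exp(-k N t)`, optionally
  with lognormal counting noise, for exercising the Schlesinger
  estimator, which inverts the noiseless curve exactly.

The twenty published per-run regression rows are shipped verbatim as a
fixture (typeset minus signs normalized on input); their summary rows
are never stored, always recomputed.

## Known limitations

* Continuous-space Brownian motion, bacterial motility, reversible
  adsorption and receptor heterogeneity are out of scope; the kinetics
  calculators treat `f` as a single constant.
* The microcolony ratio `n^(1/3)` assumes volume-additive close packing
  (colony radius exactly proportional to the cube root of cell number)
  and radius-linear encounter scaling.
* Units follow the cm/mL/min convention throughout, with `k` in cm³/min;
  the historical `2.3 * log10` display form of the Schlesinger estimator
  is reported alongside the canonical `ln` form (2.3 being rounded
  ln 10). Whether adsorption rate constants are better viewed as mL/min
  or mL⁻¹·min⁻¹ is a recorded ambiguity the package does not
  adjudicate.
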