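# phagewalk

Simulation and analysis of phage–bacterium encounter rates: does the rate
at which a diffusing phage virion finds a motionless bacterium scale with
the cell's radius (R¹) or with its surface area (R²)?

## The problem

The adsorption of phage virions to bacteria is the first pharmacodynamic
step of phage therapy. For a motionless spherical cell the
diffusion-limited (Smoluchowski-type) theory gives the adsorption rate
constant

    k = 4 π R C f        [cm³/min]

with R the cell radius (cm), C the virion diffusion rate (cm²/min) and f
the probability of attachment given encounter. The striking feature is
the *linear* dependence on R: intuition from ballistic collision theory
(Z ∝ P·N·(R_P + R_N)², a collisional cross-section) instead suggests R².
A factor-of-two difference in diameter then predicts either a two-fold or
a four-fold difference in encounter rate — which matters when dosing
phages against enlarged cells, filaments or spherical microcolonies.

`phagewalk` settles the question in silico: a point virion performs a
unit-step random walk on the integer lattice `[0, L-1]³` (six possible
moves, boundary moves restricted to stay inside the cube), starting at a
corner, and the walk ends the first time its distance D to the cube
centre drops strictly below R (an absorbing sphere). Mean step counts
over technical repeats, swept over a radius schedule and normalized to
the R = 10 reference, are regressed against the 1/R¹ and 1/R²
predictions; slopes near 1 and higher Pearson correlations identify the
correct scaling law. Per-run fits are aggregated into comparison tables
with two-tailed Welch t-tests between the two predictors. An exact
mean first-passage oracle (sparse linear solve of τ = 1 + Pτ, lattices up
to L = 25) validates the Monte Carlo core, and closed-form kinetics
calculators cover the rate constant, the Schlesinger estimator
k = ln(P₀/P_t)/(N·t), the mean free time 1/(kN), and cube-root
microcolony scaling n^(1/3).

## Worked example

```r
library(phagewalk)

spec <- experiment_spec(300, c(10, 15, 20, 30), repeats = 200,
                        master_seed = 42, reference_radius = 10)
e <- run_experiment(spec, keep_steps = FALSE)
print(e)
#> Encounter experiment: L = 300, 4 radii (10..30), 200 repeats, seed 42
#>  radius mean_steps  sd_steps   n n_capped
#>      10  1288556.2 1366587.0 200        0
#>      15   734421.4  700845.2 200        0
#>      20   570712.2  486926.7 200        0
#>      30   343152.6  270166.1 200        0

fit <- encounter_fit(relative_curve(e), reference_radius = 10)
print(fit)
#> Encounter-rate scaling comparison (1 run, radii 10..30, ref 10)
#>        run     m_R1     b_R1     r_R1     m_R2     b_R2     r_R2
#>          1   1.0932 -11.3465   0.9952   0.7977  20.9726   0.9961
#>  ...
```

Mean steps fall from 1.29×10⁶ at R = 10 to 3.4×10⁵ at R = 30 — a 3.8-fold
drop for a 3-fold radius increase, far from the 9-fold drop an R² law
would give. The slope against the 1/R¹ prediction (`m_R1 = 1.09`) is near
1, while the 1/R² slope is depressed (`m_R2 = 0.80`): the encounter rate
tracks the radius, not the surface area.

The kinetics calculators work in the cm/mL/min convention:

```r
k <- k_theoretical(R = 5e-5, C = 4e-6, f = 1)   # 2.513e-09 mL/min
mean_free_time(k, N = 1e7)                      # 39.79 min
cluster_rate_ratio(1000)                        # 10: a 1000-cell colony is
                                                # found only 10x faster
```

A command-line front end wrapping the same functions is installed at
`system.file("cli", "phagewalk.R", package = "phagewalk")` with
subcommands `simulate`, `compare`, `reanalyze`, `kinetics` and
`fixtures`; see `?cli_main`.

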