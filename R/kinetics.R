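#' Theoretical phage adsorption rate constant
#'
#' Diffusion-limited (Smoluchowski-type) rate constant for virions reaching
#' a motionless spherical bacterium: `k = 4*pi*R*C*f`. Note the linear
#' dependence on the cell radius R — not on its surface area.
#'
#' @param R Bacterial radius, cm.
#' @param C Virion diffusion rate, cm^2/min (often written D).
#' @param f Probability of attachment given encounter, in \[0, 1\].
#' @return k in cm^3/min (equivalently mL/min).
#' @examples
#' k_theoretical(R = 1e-4, C = 2.4e-6, f = 1)
#' @export
k_theoretical <- function(R, C, f) {
  if (any(R <= 0) || any(C <= 0))
    stop("`R` and `C` must be positive", call. = FALSE)
  if (any(f < 0 | f > 1))
    stop("`f` must lie in [0, 1]", call. = FALSE)
  4 * pi * R * C * f
}

#' Empirical adsorption rate constant (Schlesinger estimator)
#'
#' Inverts exponential free-phage decay: with bacterial concentration `N`
#' (per mL) held constant, free phage decline as
#' `P_t = P0 * exp(-k*N*t)`, so `k = ln(P0/Pt) / (N*t)`. The historical
#' display form uses `2.3 * log10` in place of `ln` (2.3 being rounded
#' ln 10 = 2.3026); the natural-log form is canonical here and the display
#' form is returned alongside it.
#'
#' @param N Bacterial concentration, per mL.
#' @param t Adsorption time, min.
#' @param P0,Pt Free-phage concentrations at time 0 and t, per mL;
#'   `0 < Pt`, and `Pt <= P0` for adsorption (a warning is issued when
#'   `Pt > P0`, which yields a negative k, i.e. apparent growth).
#' @return List with `k` (cm^3/min, the ln form) and `k_display`
#'   (the 2.3*log10 form).
#' @examples
#' k_schlesinger(N = 1e8, t = 10, P0 = 1e6, Pt = 5e5)
#' @export
k_schlesinger <- function(N, t, P0, Pt) {
  if (any(N <= 0) || any(t <= 0))
    stop("`N` and `t` must be positive", call. = FALSE)
  if (any(Pt <= 0))
    stop("`Pt` must be positive (complete adsorption has no finite k)",
         call. = FALSE)
  if (any(Pt > P0))
    warning("Pt > P0 yields negative k (growth, not adsorption)")
  list(k = log(P0 / Pt) / (N * t),
       k_display = 2.3 * log10(P0 / Pt) / (N * t))
}

#' Phage mean free time
#'
#' Expected time for one phage to reach a bacterium at bacterial
#' concentration `N`: `1 / (k * N)` minutes. Under the theoretical
#' `k = 4*pi*R*C*f` this is proportional to 1/R at fixed C, f, N — the
#' scaling probed by the lattice simulation.
#'
#' @param k Adsorption rate constant, cm^3/min.
#' @param N Bacterial concentration, per mL.
#' @return Minutes; `Inf` (with a message) when `k` or `N` is zero.
#' @export
mean_free_time <- function(k, N) {
  if (any(k < 0) || any(N < 0))
    stop("`k` and `N` must be non-negative", call. = FALSE)
  if (any(k == 0) || any(N == 0)) {
    message("zero rate or concentration: mean free time is infinite")
    return(Inf)
  }
  1 / (k * N)
}

#' Relative collision frequency
#'
#' Gas-kinetic collision-frequency proportionality for two particle
#' species: `Z ~ P * N * (RP + RN)^2` — the R^2 ("collisional cross
#' section") intuition that the lattice simulation tests against the
#' diffusion-limited R^1 result. With `RP = 0` (virion size ignored,
#' bacteria much larger) this reduces to `P * N * RN^2`.
#'
#' @param P,N Concentrations of the two species.
#' @param RP,RN Radii of the two species, cm.
#' @return Relative frequency (no absolute prefactor).
#' @export
collision_frequency_rel <- function(P, N, RP, RN) {
  if (any(c(P, N, RP, RN) < 0))
    stop("all inputs must be non-negative", call. = FALSE)
  P * N * (RP + RN)^2
}

#' Microcolony encounter-rate ratio
#'
#' A close-packed spherical microcolony of `n` cells, occupying no more
#' volume than the cells in isolation, has radius proportional to n^(1/3);
#' under radius-linear (R^1) encounter scaling its encounter rate relative
#' to a single cell is therefore `n^(1/3)`. A 1000-cell colony is reached
#' only ten-fold faster than an isolated cell.
#'
#' @param n_cells Cells per microcolony, >= 1.
#' @return Predicted rate ratio.
#' @examples
#' cluster_rate_ratio(1000)  # 10
#' @export
cluster_rate_ratio <- function(n_cells) {
  if (any(n_cells < 1))
    stop("`n_cells` must be >= 1", call. = FALSE)
  n_cells^(1 / 3)
}

#' Generic size-scaling rate ratio
#'
#' Rate ratio implied by a volume (or size) factor raised to a scaling
#' exponent: `volume_factor^exponent`. Covers, e.g., the penicillin
#' comparison (four-fold larger cells, observed ratio about
#' 4^0.25 = 1.41) against theoretical bounds 4^0.5 = 2 to 4^0.8 = 3.
#'
#' @param volume_factor Positive size factor.
#' @param exponent Real scaling exponent.
#' @return `volume_factor^exponent`.
#' @export
size_scaling_ratio <- function(volume_factor, exponent) {
  if (any(volume_factor <= 0))
    stop("`volume_factor` must be positive", call. = FALSE)
  volume_factor^exponent
}
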