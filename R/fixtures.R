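#' Published per-run comparison-table rows
#'
#' Loads the twenty published per-run regression rows shipped with the
#' package: ten independent simulation runs for radii 10-1000 in a
#' 2500-unit cube (`table = 1`) and ten for radii 10-30 in a 500-unit cube
#' (`table = 2`), each with slope, intercept and Pearson r against the
#' 1/R and 1/R^2 predictions. Summary rows (means, SDs, p-values) are
#' deliberately not stored; they are recomputed from the per-run rows by
#' [encounter_fit_from_rows()] / [comparison_table()].
#'
#' @param which `1`, `2`, or `"both"`.
#' @return Data frame with columns `table`, `run`, `m_R1`, `b_R1`, `r_R1`,
#'   `m_R2`, `b_R2`, `r_R2`.
#' @export
printed_tables <- function(which = "both") {
  path <- system.file("extdata", "tables_fixture.csv", package = "phagewalk")
  tab <- read_fit_rows_csv(path)
  if (!identical(which, "both")) tab <- tab[tab$table == which, ]
  tab
}

#' Wrap externally fitted rows as an encounter fit
#'
#' Builds an [encounter_fit()] object directly from per-run m/b/r rows
#' (e.g. the shipped published rows, or a CSV of fits produced elsewhere),
#' so the comparison-table machinery — means, SDs, two-tailed t-tests —
#' applies to them unchanged.
#'
#' @param rows Data frame with columns `m_R1`, `b_R1`, `r_R1`, `m_R2`,
#'   `b_R2`, `r_R2` (an optional `run` column is kept; exponent suffixes
#'   other than 1 and 2 are honoured via `exponents`).
#' @param exponents Exponents present in the column suffixes.
#' @param t_variant Variant passed to [welch_t_two_tailed()].
#' @return An `encounter_fit` object (without radii/curves).
#' @export
encounter_fit_from_rows <- function(rows, exponents = c(1, 2),
                                    t_variant = "welch") {
  need <- as.vector(outer(c("m", "b", "r"), exponents,
                          function(q, p) sprintf("%s_R%g", q, p)))
  if (!all(need %in% names(rows)))
    stop("missing columns: ", paste(setdiff(need, names(rows)),
                                    collapse = ", "), call. = FALSE)
  out <- rows[need]
  out <- cbind(run = if ("run" %in% names(rows)) rows$run
               else seq_len(nrow(rows)), out)
  structure(list(rows = out, exponents = exponents,
                 reference_radius = NA_real_, radii = NULL,
                 t_variant = t_variant),
            class = "encounter_fit")
}

#' Synthetic fixture generators
#'
#' Seeded generators for the data shapes the analysis consumes, used by
#' the test-suite and available for experimentation:
#' \describe{
#'   \item{`size_rate_sqrt`}{Pairs (size, rate) with
#'     `rate = a * sqrt(size) + Gaussian(0, noise_sd)`, emulating
#'     surface-area versus normalized-adsorption-rate measurements in
#'     which the rate actually follows the square root of the area
#'     (i.e. the radius). Defaults: n = 7 growth conditions, sizes spread
#'     over roughly a four-fold area range, a = 0.03, noise_sd = 0.005.}
#'   \item{`decay_curve`}{Free-phage decay samples (t, P_t) from
#'     `P0 * exp(-k*N*t)`, optionally with multiplicative lognormal
#'     counting noise, for exercising the Schlesinger estimator.}
#'   \item{`tables_printed`}{The shipped published per-run rows
#'     (see [printed_tables()]); ignores `n` and `noise_sd`.}
#' }
#'
#' @param name Generator name.
#' @param n Number of points.
#' @param noise_sd Noise standard deviation (additive for
#'   `size_rate_sqrt`; lognormal sdlog for `decay_curve`).
#' @param seed Integer seed (generators are reproducible).
#' @param a Slope of the sqrt law (`size_rate_sqrt`).
#' @param k,N,P0 Decay parameters (`decay_curve`).
#' @param t_max Last sample time, min (`decay_curve`).
#' @return Data frame (`size`,`rate`), (`t`,`P_t`), or the fixture rows.
#' @export
generate_fixture <- function(name, n = 7, noise_sd = 0.005, seed = 1,
                             a = 0.03, k = 2.5e-9, N = 1e8, P0 = 1e6,
                             t_max = 20) {
  known <- c("size_rate_sqrt", "decay_curve", "tables_printed")
  if (!name %in% known)
    stop("unknown generator '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  switch(name,
    size_rate_sqrt = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      size <- seq(0.5, 2, length.out = n)   # ~4-fold area range
      rate <- a * sqrt(size) + stats::rnorm(n, 0, noise_sd)
      data.frame(size = size, rate = rate)
    },
    decay_curve = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      t <- seq(0, t_max, length.out = n)
      P_t <- P0 * exp(-k * N * t)
      if (noise_sd > 0)
        P_t <- P_t * exp(stats::rnorm(n, 0, noise_sd))
      data.frame(t = t, P_t = P_t)
    },
    tables_printed = printed_tables())
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
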