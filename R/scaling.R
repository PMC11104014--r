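#' Predicted relative encounter-step curve under 1/R^p scaling
#'
#' If the mean free time of the search scales as 1/R^p, the predicted
#' relative step count is `100 * (R_ref / R)^p`. The diffusion-limited
#' (Smoluchowski) theory gives p = 1; the surface-area ("collisional cross
#' section") intuition gives p = 2.
#'
#' @param radii Radii at which to evaluate the prediction.
#' @param p Scaling exponent, 1 or 2 (any real exponent is accepted with
#'   `generalized = TRUE`).
#' @param reference_radius Radius at which the prediction is anchored
#'   at 100.
#' @param generalized Allow exponents outside {1, 2}.
#' @return Data frame with columns `radius`, `values_percent`, of class
#'   `prediction_curve`; exponent kept as attribute `p`.
#' @export
prediction_curve <- function(radii, p, reference_radius,
                             generalized = FALSE) {
  if (!generalized && !p %in% c(1, 2))
    stop("`p` must be 1 or 2 (set `generalized = TRUE` for other exponents)",
         call. = FALSE)
  if (any(radii <= 0) || reference_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  out <- data.frame(radius = radii,
                    values_percent = 100 * (reference_radius / radii)^p)
  attr(out, "p") <- p
  attr(out, "reference_radius") <- reference_radius
  class(out) <- c("prediction_curve", "data.frame")
  out
}

#' Ordinary least-squares fit with Pearson correlation
#'
#' Degree-1 least-squares fit of `y` on `x`, reporting slope `m`, intercept
#' `b` and the Pearson correlation coefficient `r` — the three statistics
#' used throughout the scaling comparison tables.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points.
#' @return List of class `fit_result` with elements `m`, `b`, `r`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate fit: constant x or y", call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  structure(list(m = unname(co[2]), b = unname(co[1]),
                 r = stats::cor(x, y)),
            class = "fit_result")
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit: m = %.*f, b = %.*f, r = %.*f\n",
              digits, x$m, digits, x$b, digits, x$r))
  invisible(x)
}

#' Two-tailed two-sample t-test p-value
#'
#' The comparison tables test, column by column, whether the fit statistics
#' obtained against the 1/R prediction differ from those obtained against
#' the 1/R^2 prediction across independent runs. The default is the
#' unpaired unequal-variance (Welch) test with Welch-Satterthwaite degrees
#' of freedom; pooled-variance and paired variants are available for
#' comparison.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variant `"welch"` (default), `"pooled"` or `"paired"`.
#' @return Two-tailed p-value in (0, 1]. If both samples have zero variance
#'   the p-value is 1 when the means are equal and 0 (the limiting value,
#'   with a warning) otherwise.
#' @export
welch_t_two_tailed <- function(a, b, variant = c("welch", "pooled", "paired")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs >= 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    warning("zero variance in both samples with unequal means; ",
            "p-value reported as the limiting value 0")
    return(0)
  }
  switch(variant,
    welch  = stats::t.test(a, b, var.equal = FALSE)$p.value,
    pooled = stats::t.test(a, b, var.equal = TRUE)$p.value,
    paired = stats::t.test(a, b, paired = TRUE)$p.value)
}

#' Fit the R^1-versus-R^2 scaling comparison
#'
#' The central estimator: for each independent simulation run, the relative
#' encounter-step curve (y, percent of the reference radius) is regressed
#' on the 1/R^p predicted curve (x, also percent) for each exponent, giving
#' per-run slope m, intercept b and Pearson r. Across runs the table
#' reports column means, standard deviations (n-1), and two-tailed t-test
#' p-values comparing each statistic between the two exponents — the shape
#' of the study's comparison tables. A slope near 1 with r near 1 for p = 1,
#' against a depressed slope and r for p = 2, is the diffusion-limited
#' (radius-linear) signature.
#'
#' @param curves A list of [relative_curve()] data frames (one per
#'   independent run), or a single curve; all runs must share one radius
#'   schedule. `encounter_experiment` objects are accepted and converted.
#' @param reference_radius Reference radius anchoring the predictions;
#'   defaults to the attribute recorded on the first curve.
#' @param exponents Scaling exponents to compare (default `c(1, 2)`).
#' @param t_variant Variant passed to [welch_t_two_tailed()].
#' @return Object of class `encounter_fit`: list with `rows` (data frame
#'   of per-run m/b/r per exponent), `exponents`, `reference_radius`,
#'   `t_variant`. Means, SDs and p-values are always recomputed from
#'   `rows` by the accessors, never cached.
#' @seealso [comparison_table()] for the assembled table,
#'   [coef.encounter_fit()], [print.encounter_fit()].
#' @export
encounter_fit <- function(curves, reference_radius = NULL,
                          exponents = c(1, 2),
                          t_variant = c("welch", "pooled", "paired")) {
  t_variant <- match.arg(t_variant)
  if (inherits(curves, "encounter_experiment") ||
      inherits(curves, "relative_curve"))
    curves <- list(curves)
  curves <- lapply(curves, function(cv) {
    if (inherits(cv, "encounter_experiment")) relative_curve(cv) else cv
  })
  if (length(curves) < 1) stop("need at least one run", call. = FALSE)
  radii <- curves[[1]]$radius
  for (cv in curves)
    if (length(cv$radius) != length(radii) ||
        any(abs(cv$radius - radii) > 1e-9))
      stop("all runs must share an identical radius schedule", call. = FALSE)
  if (is.null(reference_radius))
    reference_radius <- attr(curves[[1]], "reference_radius")
  if (is.null(reference_radius))
    stop("`reference_radius` required", call. = FALSE)

  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    y <- curves[[i]]$relative_percent
    row <- data.frame(run = i)
    for (p in exponents) {
      x <- prediction_curve(radii, p, reference_radius,
                            generalized = TRUE)$values_percent
      f <- ols_fit(x, y)
      row[[sprintf("m_R%g", p)]] <- f$m
      row[[sprintf("b_R%g", p)]] <- f$b
      row[[sprintf("r_R%g", p)]] <- f$r
    }
    row
  }))
  structure(list(rows = rows, exponents = exponents,
                 reference_radius = reference_radius,
                 radii = radii, t_variant = t_variant),
            class = "encounter_fit")
}

#' Assemble the comparison table of an encounter fit
#'
#' Recomputes column means, standard deviations and (for exactly two
#' exponents) two-tailed t-test p-values from the per-run rows. With a
#' single run the dispersion and p-value rows are `NA` (not applicable).
#'
#' @param fit An [encounter_fit()].
#' @return List with `rows`, `means`, `sds`, `p_values` (named vector
#'   `p_m`, `p_b`, `p_r`, or `NA` when inapplicable).
#' @export
comparison_table <- function(fit) {
  stopifnot(inherits(fit, "encounter_fit"))
  rows <- fit$rows
  stat_cols <- setdiff(names(rows), "run")
  means <- vapply(rows[stat_cols], mean, 0)
  sds <- if (nrow(rows) > 1) vapply(rows[stat_cols], stats::sd, 0)
         else stats::setNames(rep(NA_real_, length(stat_cols)), stat_cols)
  p_values <- c(p_m = NA_real_, p_b = NA_real_, p_r = NA_real_)
  if (length(fit$exponents) == 2 && nrow(rows) > 1) {
    p1 <- fit$exponents[1]; p2 <- fit$exponents[2]
    for (q in c("m", "b", "r")) {
      a <- rows[[sprintf("%s_R%g", q, p1)]]
      b <- rows[[sprintf("%s_R%g", q, p2)]]
      p_values[paste0("p_", q)] <-
        welch_t_two_tailed(a, b, fit$t_variant)
    }
  }
  list(rows = rows, means = means, sds = sds, p_values = p_values)
}

#' @method print encounter_fit
#' @export
print.encounter_fit <- function(x, digits = 4, ...) {
  tab <- comparison_table(x)
  where <- if (is.null(x$radii)) "externally fitted rows"
           else sprintf("radii %g..%g, ref %g", min(x$radii), max(x$radii),
                        x$reference_radius)
  cat(sprintf("Encounter-rate scaling comparison (%d run%s, %s)\n",
              nrow(tab$rows), if (nrow(tab$rows) == 1) "" else "s", where))
  rows <- tab$rows
  num <- rows[setdiff(names(rows), "run")]
  body <- cbind(run = as.character(rows$run), format(round(num, digits)))
  sumr <- rbind(
    c("Means:", format(round(tab$means, digits))),
    c("SDs:", format(round(tab$sds, digits))),
    c("p-values:", format(round(tab$p_values["p_m"], digits)),
      format(round(tab$p_values["p_b"], digits)),
      format(round(tab$p_values["p_r"], digits)),
      rep("NA", max(0, ncol(num) - 3))))
  colnames(sumr) <- colnames(body)
  print.data.frame(as.data.frame(rbind(body, sumr)), row.names = FALSE)
  if (length(x$exponents) == 2)
    cat(sprintf(
      "p-values: two-tailed %s t-tests between x = 1/R^%g and x = 1/R^%g\n",
      x$t_variant, x$exponents[1], x$exponents[2]))
  invisible(x)
}

#' @method summary encounter_fit
#' @export
summary.encounter_fit <- function(object, ...) {
  tab <- comparison_table(object)
  cat("Scaling fit summary\n")
  for (p in object$exponents) {
    cat(sprintf("  x = 1/R^%g : mean m = %.4f, mean b = %.4f, mean r = %.4f\n",
                p, tab$means[sprintf("m_R%g", p)],
                tab$means[sprintf("b_R%g", p)],
                tab$means[sprintf("r_R%g", p)]))
  }
  if (!all(is.na(tab$p_values)))
    cat(sprintf("  t-tests (%s): p_m = %.4g, p_b = %.4g, p_r = %.4g\n",
                object$t_variant, tab$p_values["p_m"],
                tab$p_values["p_b"], tab$p_values["p_r"]))
  invisible(list(means = tab$means, sds = tab$sds, p_values = tab$p_values))
}

#' @method coef encounter_fit
#' @export
coef.encounter_fit <- function(object, ...) {
  m <- as.matrix(object$rows[setdiff(names(object$rows), "run")])
  rownames(m) <- object$rows$run
  m
}

#' Square-root re-analysis of size-versus-adsorption-rate data
#'
#' Given paired measurements of a surface-area-like size measure and a
#' normalized adsorption rate, fits the rate against the size measure
#' (rate proportional to R^2 if size is an area) and against its square
#' root (proportional to R^1), reporting both correlation coefficients.
#' A higher r for the square-root fit favours radius-linear scaling.
#'
#' @param data Data frame with columns `size` (positive) and `rate`, at
#'   least 3 rows; see [read_size_rate_csv()].
#' @return List of class `size_rate_fit` with elements `fit_size`,
#'   `fit_sqrt` (each a [ols_fit()] result) and `data`.
#' @export
reanalyze_size_vs_rate <- function(data) {
  if (!all(c("size", "rate") %in% names(data)))
    stop("`data` needs columns `size` and `rate`", call. = FALSE)
  if (nrow(data) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (any(data$size <= 0)) stop("sizes must be positive", call. = FALSE)
  structure(list(fit_size = ols_fit(data$size, data$rate),
                 fit_sqrt = ols_fit(sqrt(data$size), data$rate),
                 data = data),
            class = "size_rate_fit")
}

#' @method print size_rate_fit
#' @export
print.size_rate_fit <- function(x, digits = 4, ...) {
  cat("Size-versus-rate re-analysis\n")
  cat(sprintf("  rate ~ size   (area, R^2-like):  m = %.*f, b = %.*f, r = %.*f\n",
              digits, x$fit_size$m, digits, x$fit_size$b, digits, x$fit_size$r))
  cat(sprintf("  rate ~ sqrt(size) (R^1-like)  :  m = %.*f, b = %.*f, r = %.*f\n",
              digits, x$fit_sqrt$m, digits, x$fit_sqrt$b, digits, x$fit_sqrt$r))
  better <- if (x$fit_sqrt$r > x$fit_size$r) "sqrt(size) (R^1)" else "size (R^2)"
  cat(sprintf("  higher correlation: %s\n", better))
  invisible(x)
}
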