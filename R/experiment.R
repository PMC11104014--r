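#' Radius schedules
#'
#' Builds the schedule of target radii swept by an experiment. `"linear"`
#' produces an arithmetic sequence `lo, lo + step, ..., hi` (e.g. 10 to 30
#' by 0.2 gives 101 sizes; 10 to 500 by 10 gives 50). `"exponential"`
#' produces the 1-2-5 decade ladder clipped to `[lo, hi]` (10 to 1000 gives
#' 10, 20, 50, 100, 200, 500, 1000); when `step_or_count` is supplied for an
#' exponential schedule and differs from the ladder length, a geometric
#' sequence of that many points is returned instead.
#'
#' @param kind `"linear"` or `"exponential"`.
#' @param lo,hi Positive schedule bounds, `lo < hi`.
#' @param step_or_count Step size (linear) or point count (exponential,
#'   optional).
#' @return Numeric vector of radii, strictly increasing.
#' @export
radius_schedule <- function(kind = c("linear", "exponential"), lo, hi,
                            step_or_count = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= 0 || lo >= hi)
    stop("need 0 < lo < hi", call. = FALSE)
  if (kind == "linear") {
    if (is.null(step_or_count) || step_or_count <= 0)
      stop("linear schedule needs a positive step", call. = FALSE)
    n <- round((hi - lo) / step_or_count)
    lo + step_or_count * (0:n)             # avoids seq() FP endpoint drop
  } else {
    decades <- floor(log10(lo)):ceiling(log10(hi))
    ladder <- sort(as.vector(outer(c(1, 2, 5), 10^decades)))
    ladder <- ladder[ladder >= lo & ladder <= hi]
    if (!is.null(step_or_count) && step_or_count != length(ladder)) {
      if (step_or_count < 2) stop("need at least 2 points", call. = FALSE)
      10^seq(log10(lo), log10(hi), length.out = step_or_count)
    } else ladder
  }
}

#' Specify a Monte Carlo encounter experiment
#'
#' An experiment sweeps a schedule of target radii inside a fixed cube,
#' running `repeats` technical repeats (independent walks) per radius and
#' averaging the step counts. Per-walk RNG streams are derived from
#' `(master_seed, run_index, radius index, repeat index)` so results are
#' reproducible and invariant to execution order, and extending the
#' schedule never perturbs existing streams.
#'
#' @param edge_length Cube edge in lattice units.
#' @param radii Strictly increasing radii, each `< edge_length/2`.
#' @param repeats Technical repeats per radius (study values: 100 or 200).
#' @param master_seed Integer seed.
#' @param reference_radius Radius that anchors relative curves at 100
#'   percent (default 10, the smallest size at which the discrete grid
#'   approximates the sphere acceptably).
#' @param run_index Integer tag kept in the RNG key so that independent
#'   runs of the same spec draw disjoint streams.
#' @inheritParams walk_config
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(edge_length, radii, repeats, master_seed,
                            reference_radius = 10, run_index = 0L,
                            start_mode = "corner", max_steps = 1e10,
                            boundary_policy = "reflect") {
  if (length(radii) < 1L || any(!is.finite(radii)) || any(radii <= 0))
    stop("`radii` must be positive", call. = FALSE)
  if (is.unsorted(radii, strictly = TRUE))
    stop("`radii` must be strictly increasing", call. = FALSE)
  if (any(radii >= edge_length / 2))
    stop("every radius must be < edge_length/2", call. = FALSE)
  if (!any(abs(radii - reference_radius) < 1e-9))
    stop("`reference_radius` must be one of `radii`", call. = FALSE)
  if (length(repeats) != 1L || repeats < 1 || repeats != floor(repeats))
    stop("`repeats` must be a positive integer", call. = FALSE)
  # validates geometry once via the largest radius
  walk_config(edge_length, max(radii), start_mode, max_steps, boundary_policy)
  structure(
    list(edge_length = as.integer(edge_length), radii = as.numeric(radii),
         repeats = as.integer(repeats), master_seed = as.numeric(master_seed),
         reference_radius = as.numeric(reference_radius),
         run_index = as.integer(run_index), start_mode = start_mode,
         max_steps = as.numeric(max_steps), boundary_policy = boundary_policy),
    class = "experiment_spec")
}

#' Run a Monte Carlo encounter experiment
#'
#' For each radius in the schedule, runs the configured number of technical
#' repeats of the lattice walk and records the mean and standard deviation
#' (n-1 denominator) of the step counts. Fully reproducible from the spec.
#'
#' @param spec An [experiment_spec()].
#' @param keep_steps Keep the per-walk step counts (list column `steps`);
#'   default `TRUE` below 10^4 total walks.
#' @param progress Print one line per radius while running.
#' @return An object of class `encounter_experiment`: a data frame with
#'   columns `radius`, `mean_steps`, `sd_steps`, `n`, `n_capped`, carrying
#'   the spec as an attribute. `n_capped` counts walks that hit the step
#'   cap; any non-zero value taints downstream analysis (see
#'   [relative_curve()]).
#' @export
run_experiment <- function(spec, keep_steps = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  res <- vector("list", length(spec$radii))
  for (i in seq_along(spec$radii)) {
    res[[i]] <- .radius_summary(spec, i)
    if (progress)
      message(sprintf("radius %g: mean %.4g steps over %d repeats",
                      res[[i]]$radius, res[[i]]$mean_steps, spec$repeats))
  }
  .assemble_experiment(res, spec, keep_steps)
}

# one radius of an experiment; RNG stream is keyed by the radius *index*
# so schedules can be extended without perturbing existing streams
.radius_summary <- function(spec, i) {
  steps <- cpp_walk_batch(spec$edge_length, spec$radii[i], spec$repeats,
                          spec$max_steps, spec$master_seed, spec$run_index,
                          i - 1L, spec$start_mode == "corner",
                          spec$boundary_policy == "stay")
  ok <- steps[!is.na(steps)]
  list(radius = spec$radii[i],
       mean_steps = mean(ok),
       sd_steps = if (length(ok) > 1) stats::sd(ok) else 0,
       n = spec$repeats, n_capped = sum(is.na(steps)),
       steps = steps)
}

.assemble_experiment <- function(res, spec, keep_steps = NULL) {
  if (is.null(keep_steps))
    keep_steps <- length(res) * spec$repeats <= 1e4
  out <- data.frame(radius = vapply(res, `[[`, 0, "radius"),
                    mean_steps = vapply(res, `[[`, 0, "mean_steps"),
                    sd_steps = vapply(res, `[[`, 0, "sd_steps"),
                    n = vapply(res, `[[`, 0L, "n"),
                    n_capped = vapply(res, function(x) as.integer(x$n_capped),
                                      0L))
  if (any(out$n == 1L)) attr(out, "degenerate_sample") <- TRUE
  if (keep_steps) attr(out, "steps") <- lapply(res, `[[`, "steps")
  attr(out, "spec") <- spec
  class(out) <- c("encounter_experiment", "data.frame")
  out
}

#' @method print encounter_experiment
#' @export
print.encounter_experiment <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "Encounter experiment: L = %d, %d radii (%g..%g), %d repeats, seed %g\n",
    spec$edge_length, nrow(x), min(x$radius), max(x$radius), spec$repeats,
    spec$master_seed))
  print.data.frame(x, row.names = FALSE, ...)
  if (any(x$n_capped > 0))
    cat("Warning: some walks hit the step cap; means are truncated.\n")
  invisible(x)
}

#' @method summary encounter_experiment
#' @export
summary.encounter_experiment <- function(object, ...) {
  spec <- attr(object, "spec")
  rel <- relative_curve(object, force = TRUE)
  cat(sprintf("Encounter experiment (L = %d, %d repeats per radius)\n",
              spec$edge_length, spec$repeats))
  cat(sprintf("  radii        : %g .. %g (%d sizes)\n",
              min(object$radius), max(object$radius), nrow(object)))
  cat(sprintf("  mean steps   : %.4g at R = %g down to %.4g at R = %g\n",
              object$mean_steps[1], object$radius[1],
              object$mean_steps[nrow(object)], object$radius[nrow(object)]))
  cat(sprintf("  relative (%%) : 100 at R = %g down to %.3g at R = %g\n",
              spec$reference_radius,
              rel$relative_percent[nrow(rel)], rel$radius[nrow(rel)]))
  invisible(object)
}

#' @method plot encounter_experiment
#' @export
plot.encounter_experiment <- function(x, relative = TRUE, predict_p = 1, ...) {
  spec <- attr(x, "spec")
  if (relative) {
    rel <- relative_curve(x, force = TRUE)
    plot(rel$radius, rel$relative_percent, type = "b", pch = 16,
         xlab = "target radius R (lattice units)",
         ylab = sprintf("steps to encounter (%% of R = %g)",
                        spec$reference_radius), ...)
    for (p in predict_p) {
      pred <- prediction_curve(x$radius, p, spec$reference_radius)
      graphics::lines(pred$radius, pred$values_percent, lty = 1 + p,
                      col = "grey40")
    }
    graphics::legend("topright", bty = "n",
                     legend = c("simulation",
                                sprintf("1/R^%d prediction", predict_p)),
                     lty = c(1, 1 + predict_p),
                     pch = c(16, rep(NA, length(predict_p))),
                     col = c("black", rep("grey40", length(predict_p))))
  } else {
    plot(x$radius, x$mean_steps, type = "b", pch = 16,
         xlab = "target radius R (lattice units)",
         ylab = "mean steps to encounter", ...)
  }
  invisible(x)
}

#' Relative encounter-step curve
#'
#' Expresses mean steps to encounter as a percentage of the mean at the
#' reference radius: `100 * mean_steps(R) / mean_steps(reference)`. The
#' curve equals 100 exactly at the reference radius.
#'
#' @param experiment An [run_experiment()] result, or a data frame with
#'   columns `radius` and `mean_steps`.
#' @param reference_radius Reference radius; defaults to the one recorded
#'   in the experiment spec.
#' @param force Proceed even if some walks hit the step cap (their means
#'   are truncated and the curve is biased low).
#' @return Data frame with columns `radius`, `mean_steps`,
#'   `relative_percent`, of class `relative_curve`.
#' @export
relative_curve <- function(experiment, reference_radius = NULL, force = FALSE) {
  spec <- attr(experiment, "spec")
  if (is.null(reference_radius)) {
    if (is.null(spec))
      stop("`reference_radius` required when no spec is attached",
           call. = FALSE)
    reference_radius <- spec$reference_radius
  }
  if (!force && !is.null(experiment$n_capped) && any(experiment$n_capped > 0))
    stop("experiment contains capped walks; rerun with a larger ",
         "`max_steps` or pass `force = TRUE`", call. = FALSE)
  i <- which(abs(experiment$radius - reference_radius) < 1e-9)
  if (length(i) != 1L)
    stop("`reference_radius` not present in the experiment", call. = FALSE)
  out <- data.frame(radius = experiment$radius,
                    mean_steps = experiment$mean_steps,
                    relative_percent =
                      100 * experiment$mean_steps / experiment$mean_steps[i])
  attr(out, "reference_radius") <- reference_radius
  class(out) <- c("relative_curve", "data.frame")
  out
}
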