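#' Run a single lattice walk
#'
#' Executes one random walk under a [walk_config()]: at each step a unit
#' move is drawn (uniformly over the feasible subset under the default
#' boundary policy), applied, and the encounter condition D < R tested.
#' The walk stops at the first encounter or when the step cap is reached.
#' Deterministic given `(config, seed)`.
#'
#' @param config A [walk_config()].
#' @param seed Integer master seed; per-walk streams are derived by a
#'   counter-based scheme (see Details).
#' @param run_index,radius_index,repeat_index Non-negative integers
#'   identifying the walk within a larger experiment; the RNG stream is a
#'   pure function of `(seed, run_index, radius_index, repeat_index)`, so
#'   repeats are independent and reproducible regardless of execution order.
#' @return A list of class `walk_outcome` with elements `steps`
#'   (non-negative count), `terminated` (`"encounter"` or `"cap_exceeded"`)
#'   and `final` (final lattice position).
#' @seealso [walk_trace()] for the full path, [fp_mean_exact()] for the
#'   exact expected step count on small lattices.
#' @export
run_walk <- function(config, seed, run_index = 0L, radius_index = 0L,
                     repeat_index = 0L) {
  stopifnot(inherits(config, "walk_config"))
  out <- cpp_run_walk(config$edge_length, config$target_radius,
                      config$max_steps, as.numeric(seed),
                      as.integer(run_index), as.integer(radius_index),
                      as.integer(repeat_index),
                      config$start_mode == "corner",
                      config$boundary_policy == "stay")
  structure(out, class = "walk_outcome")
}

#' @method print walk_outcome
#' @export
print.walk_outcome <- function(x, ...) {
  cat(sprintf("Walk outcome: %s after %g steps (final position %s)\n",
              x$terminated, x$steps, paste(x$final, collapse = ", ")))
  invisible(x)
}

#' Full trace of one walk
#'
#' Returns every visited position (row 1 is the start) of a walk identical
#' in law and in RNG stream to [run_walk()]. Intended for debugging and for
#' property checks (boundary safety, strict-encounter termination); keep
#' `config$max_steps` modest.
#'
#' @inheritParams run_walk
#' @return Integer matrix with columns `x`, `y`, `z`.
#' @export
walk_trace <- function(config, seed, run_index = 0L, radius_index = 0L,
                       repeat_index = 0L) {
  stopifnot(inherits(config, "walk_config"))
  cpp_walk_trace(config$edge_length, config$target_radius, config$max_steps,
                 as.numeric(seed), as.integer(run_index),
                 as.integer(radius_index), as.integer(repeat_index),
                 config$start_mode == "corner",
                 config$boundary_policy == "stay")
}

#' Write a walk trace as plain text
#'
#' One `x y z` line per visited position, for external inspection.
#'
#' @param trace Matrix from [walk_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
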