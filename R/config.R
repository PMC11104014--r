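#' Configure a single lattice walk
#'
#' Describes one diffusive search: a point virion performing a unit-step
#' random walk on the integer lattice `[0, edge_length-1]^3`, with an
#' absorbing sphere of radius `target_radius` at the cube centre. The walk
#' terminates the first time the virion's distance to the centre drops
#' strictly below the radius.
#'
#' @param edge_length Positive integer, cube edge in lattice units
#'   (phage-sized units). Typical study values are 500, 2500, 5000, 10000.
#' @param target_radius Positive real, absorbing-sphere radius in lattice
#'   units; must satisfy `target_radius < edge_length/2` so the sphere lies
#'   fully inside the cube.
#' @param start_mode `"corner"` (start at (0,0,0); all corners are
#'   equivalent by symmetry) or `"random_interior"` (uniform lattice point,
#'   redrawn until outside the sphere).
#' @param max_steps Step cap; a walk that exhausts it terminates with
#'   outcome `"cap_exceeded"` rather than looping silently.
#' @param boundary_policy `"reflect"` (default): at a face, edge or corner
#'   the move is drawn uniformly from the feasible subset of the six unit
#'   moves, so blocked directions are never spent as steps. `"stay"`: the
#'   move is drawn from all six; a blocked draw costs a step without
#'   movement. The two policies differ only in boundary dwell time.
#' @return An object of class `walk_config`.
#' @examples
#' cfg <- walk_config(edge_length = 100, target_radius = 10)
#' run_walk(cfg, seed = 1)
#' @export
walk_config <- function(edge_length, target_radius,
                        start_mode = c("corner", "random_interior"),
                        max_steps = 1e10,
                        boundary_policy = c("reflect", "stay")) {
  start_mode <- match.arg(start_mode)
  boundary_policy <- match.arg(boundary_policy)
  if (length(edge_length) != 1L || !is.finite(edge_length) ||
      edge_length < 1 || edge_length != floor(edge_length))
    stop("`edge_length` must be a positive integer", call. = FALSE)
  if (length(target_radius) != 1L || !is.finite(target_radius) ||
      target_radius <= 0)
    stop("`target_radius` must be positive", call. = FALSE)
  if (length(max_steps) != 1L || !is.finite(max_steps) || max_steps < 1)
    stop("`max_steps` must be >= 1", call. = FALSE)
  ctr <- lattice_center(edge_length)
  # every lattice point absorbing: the walk could never start
  if (3 * ctr[1]^2 < target_radius^2)
    stop("`target_radius` engulfs the whole cube; no non-absorbing position",
         call. = FALSE)
  if (target_radius >= edge_length / 2)
    warning("target_radius >= edge_length/2: the absorbing sphere is ",
            "clipped by the cube", call. = FALSE)
  # corner start must be outside the sphere at step 0
  if (start_mode == "corner" && sum(ctr^2) < target_radius^2)
    stop("corner start lies inside the absorbing sphere", call. = FALSE)
  structure(
    list(edge_length = as.integer(edge_length),
         target_radius = as.numeric(target_radius),
         start_mode = start_mode,
         max_steps = as.numeric(max_steps),
         boundary_policy = boundary_policy),
    class = "walk_config")
}

#' @method print walk_config
#' @export
print.walk_config <- function(x, ...) {
  cat("Lattice walk configuration\n")
  cat(sprintf("  cube edge L      : %d units\n", x$edge_length))
  cat(sprintf("  target radius R  : %g units (centre at %s)\n",
              x$target_radius,
              paste(format(lattice_center(x$edge_length)), collapse = ", ")))
  cat(sprintf("  start            : %s\n", x$start_mode))
  cat(sprintf("  boundary policy  : %s\n", x$boundary_policy))
  cat(sprintf("  step cap         : %g\n", x$max_steps))
  invisible(x)
}

#' Centre of the lattice cube
#'
#' For positions indexed `0..L-1` the geometric centre is `(L-1)/2` in each
#' coordinate, which is half-integer when `L` is even.
#'
#' @param edge_length Positive integer cube edge.
#' @return Numeric length-3 vector.
#' @examples
#' lattice_center(5)     # c(2, 2, 2)
#' lattice_center(2500)  # c(1249.5, 1249.5, 1249.5)
#' @export
lattice_center <- function(edge_length) {
  rep((edge_length - 1) / 2, 3L)
}

#' Encounter test
#'
#' A position encounters the target when its Euclidean distance to the
#' centre is strictly less than the radius (D < R); a point at exactly
#' distance R has not encountered. Comparison is done on squared distances.
#'
#' @param pos Integer vector of length 3, or an n x 3 matrix of positions.
#' @param center Numeric length-3 centre (possibly half-integer).
#' @param radius Positive radius.
#' @return Logical scalar or vector.
#' @export
is_encounter <- function(pos, center, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a positive scalar", call. = FALSE)
  if (is.matrix(pos)) {
    d2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2 +
      (pos[, 3] - center[3])^2
  } else {
    d2 <- sum((pos - center)^2)
  }
  d2 < radius^2
}

#' Feasible unit moves at a lattice position
#'
#' At the cube boundary, movement is limited to steps that keep the virion
#' inside `[0, edge_length-1]^3`: interior points admit all six unit moves,
#' faces five, edges four, corners three.
#'
#' @param pos Integer vector of length 3.
#' @param edge_length Positive integer cube edge.
#' @return Matrix with one row per feasible move (columns dx, dy, dz).
#' @export
feasible_moves <- function(pos, edge_length) {
  if (any(pos < 0) || any(pos > edge_length - 1))
    stop("position out of bounds", call. = FALSE)
  moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  colnames(moves) <- c("dx", "dy", "dz")
  cand <- sweep(moves, 2, as.numeric(pos), "+")
  keep <- rowSums(cand >= 0 & cand <= edge_length - 1) == 3L
  moves[keep, , drop = FALSE]
}
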