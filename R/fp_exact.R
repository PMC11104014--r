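#' Exact mean first-passage step count on a small lattice
#'
#' Solves the linear system tau = 1 + P %*% tau over the non-absorbing
#' lattice states, where P is the walk's transition matrix (uniform over
#' feasible moves under the reflect policy; under the stay policy blocked
#' draws contribute a self-loop). The result is the exact expected number
#' of steps to first encounter, against which Monte Carlo means can be
#' validated. The full L^3 state space is enumerated, so the solve is
#' restricted to `edge_length <= 25`.
#'
#' @param config A [walk_config()]. With `start_mode = "corner"` the value
#'   is the expectation from (0,0,0); with `"random_interior"` it is the
#'   average over all non-absorbing states (the law of the redrawn uniform
#'   start).
#' @return Expected step count (positive real).
#' @examples
#' cfg <- walk_config(5, 1.5)
#' fp_mean_exact(cfg)
#' @export
fp_mean_exact <- function(config) {
  stopifnot(inherits(config, "walk_config"))
  L <- config$edge_length
  if (L > 25)
    stop("exact solve limited to edge_length <= 25 (", L^3,
         " states requested)", call. = FALSE)
  R <- config$target_radius
  ctr <- lattice_center(L)

  coords <- as.matrix(expand.grid(x = 0:(L - 1), y = 0:(L - 1), z = 0:(L - 1)))
  absorbing <- is_encounter(coords, ctr, R)
  if (!any(absorbing))
    stop("no absorbing lattice point inside radius ", R, call. = FALSE)
  if (all(absorbing))
    stop("all lattice points absorbing; no transient states", call. = FALSE)

  n <- L^3
  idx <- function(xyz) xyz[, 1] + L * xyz[, 2] + L^2 * xyz[, 3] + 1
  trans <- which(!absorbing)
  tmap <- integer(n); tmap[trans] <- seq_along(trans)
  nt <- length(trans)

  moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  tc <- coords[trans, , drop = FALSE]

  # feasible-move count per transient state (reflect policy denominator)
  nfeas <- integer(nt)
  ii <- integer(0); jj <- integer(0)
  for (d in seq_len(6)) {
    nb <- sweep(tc, 2, moves[d, ], "+")
    ok <- rowSums(nb >= 0 & nb <= L - 1) == 3L
    nfeas <- nfeas + ok
    to <- idx(nb[ok, , drop = FALSE])
    keep <- !absorbing[to]                 # moves into the sphere leave P_tt
    ii <- c(ii, which(ok)[keep])
    jj <- c(jj, tmap[to[keep]])
  }
  stay <- config$boundary_policy == "stay"
  denom <- if (stay) rep(6, nt) else nfeas
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / denom[ii],
                            dims = c(nt, nt))
  if (stay) {
    blocked <- (6 - nfeas) / 6             # self-loop mass at the boundary
    P <- P + Matrix::Diagonal(nt, blocked)
  }
  A <- Matrix::Diagonal(nt) - P
  tau <- Matrix::solve(A, rep(1, nt))
  tau <- as.numeric(tau)

  if (config$start_mode == "corner") {
    start <- tmap[1L]                      # (0,0,0) is state 1
    if (start == 0L)
      stop("corner start is absorbing under this configuration", call. = FALSE)
    tau[start]
  } else {
    mean(tau)
  }
}
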