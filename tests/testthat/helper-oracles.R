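# Independent oracles used across the suite. These deliberately avoid the
# code paths they validate: plain-arithmetic enumeration, normal equations,
# and truncated probability propagation.

# exhaustive scalar-arithmetic count of lattice points strictly inside the
# sphere (no vectorized distance code shared with the package)
enumerate_inside <- function(L, R, center = rep((L - 1) / 2, 3)) {
  count <- 0L
  for (x in 0:(L - 1)) for (y in 0:(L - 1)) for (z in 0:(L - 1)) {
    d <- sqrt((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2)
    if (d < R) count <- count + 1L
  }
  count
}

# closed-form normal-equations OLS (slope, intercept, Pearson r)
normal_equations_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  m <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  b <- (sy - m * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(m = m, b = b, r = r)
}

# expected first-passage steps by truncated probability propagation:
# start a unit mass at the start state, push it through the one-step
# transition kernel, and accumulate E[T] = sum_t P(T > t). The kernel is
# built point-by-point from feasible_moves()/is_encounter(), independent
# of the sparse-solve construction in fp_mean_exact().
propagate_mean_steps <- function(L, R, start = c(0, 0, 0), cap = 50000,
                                 policy = "reflect") {
  center <- rep((L - 1) / 2, 3)
  n <- L^3
  id <- function(p) p[1] + L * p[2] + L^2 * p[3] + 1
  absorbing <- logical(n)
  trans_to <- vector("list", n)
  trans_pr <- vector("list", n)
  for (x in 0:(L - 1)) for (y in 0:(L - 1)) for (z in 0:(L - 1)) {
    p <- c(x, y, z)
    i <- id(p)
    absorbing[i] <- is_encounter(p, center, R)
    if (absorbing[i]) next
    mv <- feasible_moves(p, L)
    to <- apply(mv, 1, function(d) id(p + d))
    if (policy == "reflect") {
      trans_to[[i]] <- to
      trans_pr[[i]] <- rep(1 / nrow(mv), nrow(mv))
    } else {
      trans_to[[i]] <- c(to, i)
      trans_pr[[i]] <- c(rep(1 / 6, nrow(mv)), (6 - nrow(mv)) / 6)
    }
  }
  P <- matrix(0, n, n)
  for (i in which(!absorbing)) {
    P[i, trans_to[[i]]] <- P[i, trans_to[[i]]] + trans_pr[[i]]
  }
  P[, absorbing] <- 0                # absorbed mass leaves the system
  mass <- numeric(n)
  mass[id(start)] <- 1
  expected <- 0
  for (t in seq_len(cap)) {
    alive <- sum(mass)
    if (alive < 1e-14) break
    expected <- expected + alive     # adds P(T > t - 1)
    mass <- as.numeric(mass %*% P)
  }
  expected
}

# standard error of a Monte Carlo mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
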