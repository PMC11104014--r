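test_that("cube centre follows the 0..L-1 indexing convention", {
  expect_equal(lattice_center(5), c(2, 2, 2))
  expect_equal(lattice_center(2500), rep(1249.5, 3))
  expect_equal(lattice_center(1), c(0, 0, 0))
})

test_that("encounter is strictly D < R", {
  ctr <- c(10, 10, 10)
  expect_true(is_encounter(c(10, 10, 10), ctr, 0.5))    # D = 0
  expect_false(is_encounter(c(13, 10, 10), ctr, 3))     # D = R exactly
  expect_true(is_encounter(c(12, 10, 10), ctr, 3))
  expect_error(is_encounter(c(0, 0, 0), ctr, -1), "positive")
})

test_that("encounter region matches exhaustive enumeration (L = 21, R = 3)", {
  L <- 21; R <- 3
  ctr <- lattice_center(L)
  grid <- as.matrix(expand.grid(0:(L - 1), 0:(L - 1), 0:(L - 1)))
  expect_identical(sum(is_encounter(grid, ctr, R)),
                   as.integer(enumerate_inside(L, R)))
  # and on a half-integer centre
  expect_identical(sum(is_encounter(grid[grid[, 1] < 20 & grid[, 2] < 20 &
                                           grid[, 3] < 20, ],
                                    lattice_center(20), 2.5)),
                   as.integer(enumerate_inside(20, 2.5)))
})

test_that("feasible moves shrink at faces, edges and corners", {
  expect_equal(nrow(feasible_moves(c(50, 50, 50), 100)), 6)
  corner <- feasible_moves(c(0, 0, 0), 100)
  expect_equal(nrow(corner), 3)
  expect_true(all(rowSums(corner) == 1))                # +x, +y, +z only
  expect_equal(nrow(feasible_moves(c(0, 0, 5), 100)), 4)
  expect_equal(nrow(feasible_moves(c(0, 50, 50), 100)), 5)
  expect_error(feasible_moves(c(-1, 0, 0), 100), "out of bounds")
})

test_that("a walk with only corner states transient absorbs in one step", {
  cfg <- suppressWarnings(walk_config(3, 1.7))
  for (s in 1:5) {
    out <- run_walk(cfg, s)
    expect_equal(out$steps, 1)
    expect_equal(out$terminated, "encounter")
  }
  expect_equal(fp_mean_exact(cfg), 1)
})

test_that("walks are deterministic given (config, seed) and stream keys", {
  cfg <- walk_config(15, 2)
  a <- run_walk(cfg, 7, repeat_index = 3)
  b <- run_walk(cfg, 7, repeat_index = 3)
  expect_identical(a, b)
  # distinct repeat indices and distinct master seeds give distinct paths
  tr <- lapply(list(c(7, 3), c(7, 4), c(8, 3)), function(k)
    walk_trace(cfg, k[1], repeat_index = k[2]))
  expect_false(identical(tr[[1]], tr[[2]]))
  expect_false(identical(tr[[1]], tr[[3]]))
})

test_that("traces stay in bounds and terminate strictly inside the sphere", {
  for (L in c(6, 9)) {
    cfg <- walk_config(L, 1.5, max_steps = 1e6)
    ctr <- lattice_center(L)
    for (s in 1:25) {
      tr <- walk_trace(cfg, s, repeat_index = s)
      expect_true(all(tr >= 0 & tr <= L - 1))
      n <- nrow(tr)
      expect_true(is_encounter(tr[n, ], ctr, 1.5))           # final inside
      if (n > 1)
        expect_false(any(is_encounter(tr[-n, , drop = FALSE], ctr, 1.5)))
      # unit steps throughout
      if (n > 1)
        expect_true(all(rowSums(abs(diff(tr))) == 1))
    }
  }
})

test_that("trace and run_walk agree on the same stream", {
  cfg <- walk_config(9, 2)
  for (s in 1:5) {
    tr <- walk_trace(cfg, s, repeat_index = s)
    out <- run_walk(cfg, s, repeat_index = s)
    expect_equal(nrow(tr) - 1, out$steps)
    expect_equal(as.integer(tr[nrow(tr), ]), out$final)
  }
})

test_that("the stay boundary policy spends steps on blocked draws", {
  # stay policy dwells longer at the boundary, so from a corner the mean
  # first-passage time is strictly larger than under reflect
  cfg_r <- walk_config(7, 1.5, boundary_policy = "reflect")
  cfg_s <- walk_config(7, 1.5, boundary_policy = "stay")
  expect_gt(fp_mean_exact(cfg_s), fp_mean_exact(cfg_r))
  # stay-policy traces may repeat a position; reflect never does in one step
  tr <- walk_trace(cfg_s, 3)
  expect_true(all(rowSums(abs(diff(tr))) <= 1))
})

test_that("step cap yields a flagged cap_exceeded outcome", {
  cfg <- walk_config(15, 1.2, max_steps = 3)
  out <- run_walk(cfg, 1)
  expect_equal(out$terminated, "cap_exceeded")
  expect_equal(out$steps, 3)
})

test_that("random interior starts are never inside the sphere", {
  cfg <- walk_config(7, 2.5, start_mode = "random_interior")
  ctr <- lattice_center(7)
  for (s in 1:40) {
    tr <- walk_trace(cfg, s, repeat_index = s)
    expect_false(is_encounter(tr[1, ], ctr, 2.5))
    expect_gte(nrow(tr) - 1, 1)               # steps >= 1 always
  }
})

test_that("exact solve matches hand and propagation oracles", {
  # start adjacent only to absorbing states
  expect_equal(fp_mean_exact(suppressWarnings(walk_config(3, 1.7))), 1)
  # independent truncated-propagation oracle, L = 7, R = 2
  exact <- fp_mean_exact(walk_config(7, 2))
  prop <- propagate_mean_steps(7, 2)
  expect_equal(exact, prop, tolerance = 1e-10)
  # and under the stay policy
  exact_s <- fp_mean_exact(walk_config(7, 2, boundary_policy = "stay"))
  prop_s <- propagate_mean_steps(7, 2, policy = "stay")
  expect_equal(exact_s, prop_s, tolerance = 1e-10)
})

test_that("exact solve refuses oversized lattices and empty targets", {
  expect_error(fp_mean_exact(walk_config(26, 3)), "edge_length <= 25")
  expect_error(fp_mean_exact(walk_config(6, 0.5)), "no absorbing")
})

test_that("config validation enforces the geometric invariants", {
  expect_error(walk_config(0, 1), "positive integer")
  expect_error(walk_config(100, -1), "positive")
  expect_error(walk_config(100, 10, max_steps = 0), "max_steps")
  expect_warning(walk_config(5, 2.6), "clipped")
  expect_error(suppressWarnings(walk_config(5, 4)), "engulfs|corner")
})
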