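test_that("prediction curves are definitional", {
  radii <- c(10, 20, 50, 100, 200, 500, 1000)
  p1 <- prediction_curve(radii, 1, 10)
  p2 <- prediction_curve(radii, 2, 10)
  expect_equal(p1$values_percent[1], 100)
  expect_equal(p2$values_percent[1], 100)
  expect_equal(p1$values_percent[7], 1)
  expect_equal(p2$values_percent[7], 0.01)
  expect_true(all(diff(p1$values_percent) < 0))
  # p = 2 curve lies below p = 1 beyond the reference
  expect_true(all(p2$values_percent[-1] < p1$values_percent[-1]))
  expect_error(prediction_curve(radii, 3, 10), "must be 1 or 2")
  expect_silent(prediction_curve(radii, 3, 10, generalized = TRUE))
})

test_that("ols_fit matches exact lines and the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  f <- ols_fit(x, x)
  expect_equal(c(f$m, f$b, f$r), c(1, 0, 1))
  f2 <- ols_fit(x, -2 * x + 7)
  expect_equal(c(f2$m, f2$b, f2$r), c(-2, 7, -1))
  set.seed(42)
  for (i in 1:5) {
    xr <- rnorm(10); yr <- 2 * xr + rnorm(10)
    got <- ols_fit(xr, yr)
    want <- normal_equations_fit(xr, yr)
    expect_equal(got$m, want$m, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$r, want$r, tolerance = 1e-10)
  }
  expect_error(ols_fit(rep(1, 5), x), "degenerate")
  expect_error(ols_fit(x[1:2], x[1:2]), "3")
})

test_that("correlation is invariant to affine rescaling of either axis", {
  set.seed(7)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.3)
  r0 <- ols_fit(x, y)$r
  expect_equal(ols_fit(3 * x - 5, y)$r, r0)
  expect_equal(ols_fit(x, 0.1 * y + 42)$r, r0)
})

test_that("two-tailed t-test reproduces the published p-values", {
  t1 <- printed_tables(1)
  t2 <- printed_tables(2)
  expect_equal(round(welch_t_two_tailed(t1$m_R1, t1$m_R2), 4), 0.0168)
  expect_equal(round(welch_t_two_tailed(t1$r_R1, t1$r_R2), 4), 0.0004)
  expect_equal(round(welch_t_two_tailed(t2$r_R1, t2$r_R2), 4), 0.0017)
  # "0.0000" cells are bounds, not values
  expect_lt(welch_t_two_tailed(t1$b_R1, t1$b_R2), 1e-4)
  expect_lt(welch_t_two_tailed(t2$m_R1, t2$m_R2), 1e-4)
  expect_lt(welch_t_two_tailed(t2$b_R1, t2$b_R2), 1e-4)
})

test_that("t-test degenerate samples follow the limit conventions", {
  expect_equal(welch_t_two_tailed(c(1, 1), c(1, 1)), 1)
  expect_warning(p <- welch_t_two_tailed(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(p, 0)
  expect_error(welch_t_two_tailed(1, c(1, 2)), ">= 2")
})

test_that("comparison table recomputes summary rows from per-run rows", {
  fit <- encounter_fit_from_rows(printed_tables(1))
  tab <- comparison_table(fit)
  expect_equal(unname(round(tab$means["m_R1"], 4)), 1.0081)
  expect_equal(unname(round(tab$sds["m_R1"], 4)), 0.0278)
  # self-consistency at full precision against direct recomputation
  expect_equal(unname(tab$means), unname(colMeans(fit$rows[-1])),
               tolerance = 1e-12)
  expect_equal(unname(tab$sds), unname(apply(fit$rows[-1], 2, stats::sd)),
               tolerance = 1e-12)
})

test_that("single-run tables mark dispersion and tests as not applicable", {
  fit <- encounter_fit_from_rows(printed_tables(1)[1, ])
  tab <- comparison_table(fit)
  expect_true(all(is.na(tab$sds)))
  expect_true(all(is.na(tab$p_values)))
})

test_that("synthetic ensembles with known truth separate the exponents", {
  radii <- c(10, 20, 50, 100, 200, 500, 1000)
  x1 <- prediction_curve(radii, 1, 10)$values_percent
  set.seed(101)
  curves <- lapply(1:10, function(i) {
    cv <- data.frame(radius = radii,
                     relative_percent = x1 + rnorm(length(radii), sd = 2))
    cv$relative_percent[1] <- 100       # self-ratio anchor
    class(cv) <- c("relative_curve", "data.frame")
    cv
  })
  fit <- encounter_fit(curves, reference_radius = 10)
  tab <- comparison_table(fit)
  expect_lt(abs(tab$means["m_R1"] - 1), 3 * tab$sds["m_R1"])
  # the mis-specified 1/R^2 predictor is rejected at the generator's noise
  expect_lt(tab$p_values[["p_m"]], 0.05)
  expect_gt(mean(fit$rows$r_R1), mean(fit$rows$r_R2))
})

test_that("runs on mismatched radius schedules are refused", {
  cv1 <- data.frame(radius = c(10, 20, 30), relative_percent = c(100, 50, 33))
  cv2 <- data.frame(radius = c(10, 20, 40), relative_percent = c(100, 50, 25))
  expect_error(encounter_fit(list(cv1, cv2), reference_radius = 10),
               "identical radius schedule")
})

test_that("square-root reanalysis identifies the generating law", {
  size <- seq(0.5, 2, length.out = 8)
  exact_sqrt <- data.frame(size = size, rate = 0.03 * sqrt(size))
  f1 <- reanalyze_size_vs_rate(exact_sqrt)
  expect_equal(f1$fit_sqrt$r, 1)
  expect_gt(f1$fit_sqrt$r, f1$fit_size$r)
  exact_lin <- data.frame(size = size, rate = 0.03 * size)
  f2 <- reanalyze_size_vs_rate(exact_lin)
  expect_equal(f2$fit_size$r, 1)
  expect_gt(f2$fit_size$r, f2$fit_sqrt$r)
  expect_error(reanalyze_size_vs_rate(exact_lin[1:2, ]), "3")
})

test_that("sqrt fit wins on average over noisy generator replicates", {
  diffs <- vapply(1:1000, function(s) {
    d <- generate_fixture("size_rate_sqrt", seed = s)
    f <- reanalyze_size_vs_rate(d)
    f$fit_sqrt$r - f$fit_size$r
  }, 0)
  expect_gt(mean(diffs), 0)
})
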