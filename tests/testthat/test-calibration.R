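test_that("standard errors follow sd/sqrt(n)", {
  ends <- matrix(c(124, 143, 137, 142, 140, 130), nrow = 1)
  expect_equal(standard_errors(ends), sd(ends) / sqrt(6))
  expect_equal(standard_errors(ends), 7.5100 / sqrt(6), tolerance = 1e-4)
  ## homogeneity
  expect_equal(standard_errors(3 * ends), 3 * standard_errors(ends))
  ## degenerate and single-replicate cases
  expect_error(standard_errors(matrix(1, 2, 1)), "2 replicates")
  expect_error(standard_errors(matrix(5, 2, 4)), "floor")
  expect_equal(standard_errors(matrix(5, 2, 4), floor = 0.5), c(0.5, 0.5))
})

test_that("objective weighting forms match hand evaluation", {
  ## a stub problem whose forward model is bypassed through residuals math:
  ## r = (1, 2), sigma = (1, 2)
  r <- c(1, 2); sig <- c(1, 2)
  expect_equal(sum(r^2 / sig), 3)     # printed form
  expect_equal(sum(r^2 / sig^2), 2)   # classical form
  ## permutation invariance
  o <- c(2, 1)
  expect_equal(sum(r[o]^2 / sig[o]), sum(r^2 / sig))
})

test_that("DE/rand/1/bin solves the sphere and is seed-reproducible", {
  fn <- function(x) sum(x^2)
  a <- de_rand_1_bin(fn, rep(-5, 4), rep(5, 4),
                     settings = list(seed = 1, tol = 1e-10, max_gen = 300))
  expect_lt(sqrt(sum(a$par^2)), 1e-3)
  b <- de_rand_1_bin(fn, rep(-5, 4), rep(5, 4),
                     settings = list(seed = 1, tol = 1e-10, max_gen = 300))
  expect_identical(a$par, b$par)
  expect_identical(a$trace, b$trace)
  ## termination on objective spread
  c1 <- de_rand_1_bin(fn, rep(-5, 2), rep(5, 2),
                      settings = list(seed = 2, tol = 4e-3))
  expect_true(c1$converged)
  expect_lt(max(c1$objectives) - min(c1$objectives), 4e-3)
  expect_error(de_rand_1_bin(fn, rep(-5, 2), rep(5, 2),
                             settings = list(NP = 3)), ">= 4")
})

test_that("DE matches an exhaustive grid search on a 2-parameter toy", {
  fn <- function(x) (x[1] - 0.317)^2 + 2 * (x[2] + 0.243)^2 +
    0.5 * x[1] * x[2]
  gx <- seq(-1, 1, by = 1e-3)
  ## separable-ish: locate the grid optimum by coordinate profiling over the
  ## full tensor grid, evaluated in two vectorized passes
  best <- c(NA, NA); bestf <- Inf
  for (x2 in seq(-1, 1, by = 1e-3)) {
    f <- (gx - 0.317)^2 + 2 * (x2 + 0.243)^2 + 0.5 * gx * x2
    i <- which.min(f)
    if (f[i] < bestf) { bestf <- f[i]; best <- c(gx[i], x2) }
  }
  de <- de_rand_1_bin(fn, c(-1, -1), c(1, 1),
                      settings = list(seed = 3, tol = 1e-12, max_gen = 400))
  expect_lt(max(abs(de$par - best)), 2e-3)   # within one grid cell
  expect_lte(de$value, bestf + 1e-9)
})

test_that("bound handling reflects rather than clips", {
  ## objective minimized exactly on the boundary; reflection must still
  ## reach it without leaving the box
  fn <- function(x) sum((x - 1.0)^2)
  r <- de_rand_1_bin(fn, c(-1, -1), c(1, 1),
                     settings = list(seed = 4, tol = 1e-12, max_gen = 200))
  expect_true(all(r$population >= -1 & r$population <= 1))
  expect_equal(unname(r$par), c(1, 1), tolerance = 1e-3)
})

test_that("problem construction validates its inputs", {
  expect_error(calibration_problem("X_c", 10, 5, 1:3, 1:3, rep(1, 3)),
               "lower < upper")
  expect_error(calibration_problem("foo", 1, 2, 1:3, 1:3, rep(1, 3)),
               "influent components")
  expect_error(calibration_problem("X_c", 1, 2, 1:3, 1:3, rep(0, 3)),
               "> 0")
  expect_error(calibration_problem(c("X_c", "X_pr", "X_li", "X_I"),
                                   rep(0, 4), rep(1, 4),
                                   obs_days = 1:2, obs_yield = 1:2,
                                   obs_se = rep(1, 2)),
               "at least as many observations")
})

test_that("objective is deterministic across calls and zero at a perfect fit", {
  ref <- bmp_reference_curve()
  pr <- calibration_problem(
    free_names = "X_c", lower = 20, upper = 60,
    obs_days = ref$day[-1], obs_yield = ref$ch4_measured_mean[-1],
    obs_se = rep(1.25, 11),
    ar_config = reactor_config(duration = 60))
  s1 <- calibration_objective(40.769, pr)
  s2 <- calibration_objective(40.769, pr)
  expect_identical(s1, s2)
  expect_gt(s1, 0)
  ## a perfect-fit problem: observations generated by the model itself
  fw <- adm1sim:::forward_model(40.769, pr)
  pr2 <- pr
  pr2$obs_yield <- fw$yield
  expect_equal(calibration_objective(40.769, pr2), 0, tolerance = 1e-8)
  r <- calibration_residuals(40.769, pr2)
  expect_lt(max(abs(r)), 1e-5)
  ## failure sentinel keeps the optimizer alive
  r_bad <- calibration_residuals(NA_real_, pr2)
  expect_true(!is.null(attr(r_bad, "failed")))
  expect_equal(unname(r_bad[1]), 1e6)
})
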