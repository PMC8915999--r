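test_that("the B-spline basis is a partition of unity", {
  grid <- seq(30.5, 89.5, by = 1)
  for (deg in c(1, 2, 3)) {
    B <- bspline_basis(grid, spacing = 5, degree = deg)
    expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  }
})

test_that("degree-0 basis with grid-step spacing is an indicator basis", {
  grid <- seq(0.5, 9.5, by = 1)
  B <- bspline_basis(grid, spacing = 1, degree = 0, penalty_order = 1)
  expect_true(all(B %in% c(0, 1)))
  expect_true(all(rowSums(B) == 1))
  expect_true(all(colSums(B[, colSums(B) > 0]) == 1))
})

test_that("basis values match the Cox-de Boor recursion", {
  grid <- seq(30.5, 79.5, by = 1)
  B <- bspline_basis(grid, spacing = 5, degree = 3)
  knots <- attr(B, "knots")
  oracle <- sapply(seq_len(ncol(B)), function(i)
    cox_de_boor(grid, knots, 3, i))
  expect_equal(unclass(B)[, ], oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bspline_basis(c(30, 35), spacing = 100, degree = 0,
                             penalty_order = 2), "penalty_order")
})

test_that("a constant rate is recovered everywhere with large exposures", {
  set.seed(51)
  E <- matrix(2e5, 20, 10)
  D <- matrix(rpois(200, 2e5 * 0.02), 20, 10)
  g <- make_grid(seq(30, 50, 1), seq(1700, 1710, 1), D, E)
  fit <- fit_psplines_2d(g, pspline_spec(lambda_age = 10,
                                         lambda_period = 10))
  expect_true(fit$converged)
  expect_true(all(abs(exp(fit$log_rate) / 0.02 - 1) < 0.02))
})

test_that("the infinite-smoothing limit lies in the penalty null space", {
  set.seed(52)
  am <- seq(30.5, 69.5, 1); pm <- seq(1700.5, 1719.5, 1)
  true_lr <- outer(am, pm, function(a, y) -9 + 0.09 * a)
  E <- matrix(100, 40, 20)
  D <- matrix(rpois(800, 100 * exp(true_lr)), 40, 20)
  g <- make_grid(seq(30, 70, 1), seq(1700, 1720, 1), D, E)
  fit <- fit_psplines_2d(g, pspline_spec(lambda_age = 1e10,
                                         lambda_period = 1e10))
  a <- rep(am, length(pm)); p <- rep(pm, each = length(am))
  X <- cbind(1, a, p, a * p)  # null space of 2nd-order penalties in 2D
  resid <- lm.fit(X, as.numeric(fit$log_rate))$residuals
  expect_lt(max(abs(resid)), 1e-4)
})

test_that("lambda = 0 with a square indicator basis is saturated", {
  set.seed(53)
  E <- matrix(c(500, 800, 0, 600, 700, 900), 2, 3)
  D <- matrix(c(12, 20, 0, 9, 15, 22), 2, 3)
  g <- make_grid(c(30, 31, 32), c(1700, 1701, 1702, 1703), D, E)
  fit <- fit_psplines_2d(g, pspline_spec(
    spline_degree = 0, knot_spacing_age = 1, knot_spacing_period = 1,
    penalty_order = 1, lambda_age = 0, lambda_period = 0))
  pos <- E > 0
  expect_equal(exp(fit$log_rate)[pos], (D / E)[pos], tolerance = 1e-4)
})

test_that("the penalized log-likelihood never decreases across IRLS", {
  set.seed(54)
  E <- matrix(rexp(300, 1 / 40), 30, 10)
  lr <- outer(seq(30.5, 59.5), seq_len(10), function(a, j) -9.5 + 0.085 * a)
  D <- matrix(rpois(300, E * exp(lr)), 30, 10)
  g <- make_grid(seq(30, 60, 1), seq(1700, 1710, 1), D, E)
  fit <- fit_psplines_2d(g, pspline_spec(lambda_age = 5,
                                         lambda_period = 5))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("effective dimension decreases in each lambda", {
  set.seed(55)
  E <- matrix(rexp(600, 1 / 60), 40, 15)
  lr <- outer(seq(30.5, 69.5), seq_len(15),
              function(a, j) -9.2 + 0.088 * a + 0.01 * j)
  D <- matrix(rpois(600, E * exp(lr)), 40, 15)
  g <- make_grid(seq(30, 70, 1), seq(1700, 1715, 1), D, E)
  eds <- vapply(c(0.1, 10, 1000, 1e5), function(l)
    fit_psplines_2d(g, pspline_spec(lambda_age = l,
                                    lambda_period = 1))$effective_dimension,
    numeric(1))
  expect_true(all(diff(eds) < 0))
  eds_p <- vapply(c(0.1, 10, 1000, 1e5), function(l)
    fit_psplines_2d(g, pspline_spec(lambda_age = 1,
                                    lambda_period = l))$effective_dimension,
    numeric(1))
  expect_true(all(diff(eds_p) < 0))
})

test_that("BIC-based lambda selection behaves at its boundaries", {
  set.seed(56)
  E <- matrix(rexp(300, 1 / 80), 30, 10)
  lr <- matrix(-4, 30, 10)  # heavily oversmoothable truth (constant)
  D <- matrix(rpois(300, E * exp(lr)), 30, 10)
  g <- make_grid(seq(30, 60, 1), seq(1700, 1710, 1), D, E)
  single <- select_lambdas(g, pspline_spec(), lambda_grid = 42)
  expect_identical(single$lambda_age, 42)
  expect_identical(single$lambda_period, 42)
  sel <- select_lambdas(g, pspline_spec(),
                        lambda_grid = c(0.01, 1, 100, 1e4))
  tab <- attr(sel, "bic_table")
  best <- tab$bic[tab$lambda_age == sel$lambda_age &
                    tab$lambda_period == sel$lambda_period]
  expect_true(all(best <= tab$bic[tab$converged] + 1e-9))
  # a flat truth is smoothed as hard as the grid allows
  expect_identical(sel$lambda_age, 1e4)
  expect_identical(sel$lambda_period, 1e4)
})

test_that("surface aggregation is an exposure-weighted mean", {
  set.seed(57)
  E <- matrix(rexp(500, 1 / 70), 50, 10)
  D <- matrix(rpois(500, E * 0.03), 50, 10)
  g <- make_grid(seq(30, 80, 1), seq(1700, 1710, 1), D, E)
  fit <- fit_psplines_2d(g, pspline_spec(lambda_age = 50,
                                         lambda_period = 50))
  edges <- c(seq(30, 75, 5), 80)
  mx <- surface_to_mx(fit, edges, period = c(1700, 1710))
  # brute-force cellwise weighted mean oracle
  am <- fit$age_grid
  rates <- exp(fit$log_rate)
  oracle <- vapply(seq_len(length(edges) - 1L), function(i) {
    rows <- which(am >= edges[i] & am < edges[i + 1])
    sum(fit$exposures[rows, ] * rates[rows, ]) /
      sum(fit$exposures[rows, ])
  }, numeric(1))
  expect_equal(mx, oracle, tolerance = 1e-12)
  # constant surface: every group rate equals the constant
  cg <- make_grid(seq(30, 80, 1), seq(1700, 1710, 1),
                  matrix(0L, 50, 10), matrix(100, 50, 10))
  cfit <- fit_psplines_2d(cg, pspline_spec(lambda_age = 1,
                                           lambda_period = 1))
  cfit$log_rate[] <- log(0.05)
  expect_equal(surface_to_mx(cfit, edges, c(1700, 1710)),
               rep(0.05, length(edges) - 1L))
  # zero weights in a group must error, not return silent zeros
  zfit <- fit
  zfit$exposures[am >= 30 & am < 35, ] <- 0
  expect_error(surface_to_mx(zfit, edges, c(1700, 1710)), "zero total")
  expect_error(surface_to_mx(fit, edges, c(1900, 1910)), "outside")
})
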