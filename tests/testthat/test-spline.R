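test_that("degree-1 I-splines with one interior knot are unit ramps", {
  x <- seq(0, 1, 0.25)
  b <- ispline_basis(x, knots = c(0, 0.5, 1), degree = 1)
  expect_equal(b$basis[, 1], c(0, 0.5, 1, 1, 1))
  expect_equal(b$basis[, 2], c(0, 0, 0, 0.5, 1))
})

test_that("I-spline columns are monotone, bounded, and anchored", {
  set.seed(23)
  for (rep in 1:5) {
    kn <- sort(c(0, runif(4), 1))
    x <- sort(runif(300))
    b <- ispline_basis(c(0, x, 1), kn, degree = 3)
    # brute-force sort check: every column nondecreasing
    expect_true(all(apply(b$basis, 2, function(col) all(diff(col) >= -1e-12))))
    expect_true(all(b$basis >= -1e-12 & b$basis <= 1 + 1e-12))
    expect_equal(unname(b$basis[1, ]), rep(0, ncol(b$basis)))
    expect_equal(unname(b$basis[nrow(b$basis), ]),
                 rep(1, ncol(b$basis)))
  }
})

test_that("derivative columns integrate back to the basis", {
  x <- seq(0, 1, 0.001)
  b <- ispline_basis(x, knots = c(0, 0.3, 0.7, 1), degree = 3)
  # trapezoidal integration of d1 recovers the basis
  for (j in seq_len(ncol(b$basis))) {
    integ <- c(0, cumsum((b$d1[-1, j] + b$d1[-length(x), j]) / 2 * diff(x)))
    expect_lt(max(abs(integ - b$basis[, j])), 1e-4)
  }
  # and d2 is the derivative of d1
  fd <- apply(b$d1, 2, function(col) diff(col) / diff(x))
  mid <- (b$d2[-1, ] + b$d2[-length(x), ]) / 2
  expect_lt(max(abs(fd - mid)), 1e-2 * max(abs(b$d2)))
})

test_that("out-of-range evaluation points are clamped with a warning", {
  expect_warning(b <- ispline_basis(c(-1, 0.5, 2), c(0, 0.5, 1), 3),
                 "clamped")
  expect_equal(unname(b$basis[1, ]), rep(0, ncol(b$basis)))
  expect_equal(unname(b$basis[3, ]), rep(1, ncol(b$basis)))
})

test_that("a constant event rate is fitted as a near-constant curve", {
  set.seed(41)
  x <- runif(20000, 5, 40)
  y <- rbinom(20000, 1, 0.01)
  fit <- fit_shape_spline(x, y, spline_spec())
  expect_true(all(fit$p > 0.005 & fit$p < 0.02))
  # the constant model is feasible, so the fit can only do better
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("the decreasing constraint binds on data with a planted bump", {
  set.seed(42)
  pars <- risk_curve_params(0.01, 0.4, 14, 2, bump_height = 0.15,
                            bump_center = 30, bump_width = 3)
  x <- runif(15000, 2, 45)
  y <- rbinom(15000, 1, true_mortality(x, pars, tbi = TRUE))
  fit <- fit_shape_spline(x, y, spline_spec(constraint = "decreasing"))
  expect_lte(max(diff(fit$p)), 1e-10)
  expect_lte(max(fit$dp), 1e-10)
  # the unconstrained-shape fit is free to recover the bump
  fit2 <- fit_shape_spline(x, y,
                           spline_spec(constraint = "unconstrained_shape"))
  p30 <- fit2$p[which.min(abs(fit2$grid - 30))]
  p22 <- fit2$p[which.min(abs(fit2$grid - 22))]
  expect_gt(p30, p22)
})

test_that("unconstrained-shape fit with vanishing ridge matches the GLM", {
  set.seed(43)
  x <- runif(3000, 0, 30)
  y <- rbinom(3000, 1, plogis(1.5 - 0.25 * x))
  sp <- spline_spec(n_interior_knots = 2,
                    constraint = "unconstrained_shape",
                    ridge_lambda = 1e-8, tol = 1e-12, max_iter = 300)
  fit <- fit_shape_spline(x, y, sp)
  bas <- ispline_basis(x, fit$knots, 3)$basis
  glm_fit <- glm(y ~ bas, family = binomial())
  gbas <- ispline_basis(fit$grid, fit$knots, 3)$basis
  p_glm <- plogis(drop(cbind(1, gbas) %*% coef(glm_fit)))
  expect_lt(max(abs(fit$p - p_glm)), 1e-4)
})

test_that("analytic curve derivatives agree with finite differences", {
  set.seed(44)
  x <- runif(8000, 2, 40)
  y <- rbinom(8000, 1, true_mortality(x, risk_curve_params(0.01, 0.4, 14, 2)))
  fit <- fit_shape_spline(x, y, spline_spec())
  h <- fit$spec$grid_step
  n <- length(fit$grid)
  fd1 <- (fit$p[3:n] - fit$p[1:(n - 2)]) / (2 * h)
  expect_lt(max(abs(fd1 - fit$dp[2:(n - 1)])), 1e-4)
  fd2 <- (fit$p[3:n] - 2 * fit$p[2:(n - 1)] + fit$p[1:(n - 2)]) / h^2
  expect_lt(max(abs(fd2 - fit$d2p[2:(n - 1)])),
            1e-3 * max(1, max(abs(fit$d2p))))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_shape_spline(rep(1, 100), rbinom(100, 1, 0.5)),
               "distinct")
  expect_error(fit_shape_spline(runif(100), rep(0, 100)),
               class = "rsigcut_one_class_error")
})

test_that("the fit recovers the planted curve on the large cohort", {
  fix <- acceptance_fixture()
  nt <- fix$cohort[!fix$cohort$tbi, ]
  fit <- fit_shape_spline(nt$rsig, nt$died, spline_spec())
  truth <- true_mortality(pmax(fit$grid, 0),
                          fix$registry$config$curve_nontbi)
  expect_lt(sqrt(mean((fit$p - truth)^2)), 0.01)
  expect_true(fit$converged)
  expect_true(all(fit$p > 0 & fit$p < 1))
})

test_that("tidy, glance and autoplot work on fitted curves", {
  set.seed(45)
  x <- runif(2000, 5, 35)
  y <- rbinom(2000, 1, 0.2 * plogis((14 - x) / 2) + 0.005)
  fit <- fit_shape_spline(x, y)
  td <- tidy(fit)
  expect_equal(td$term[1], "intercept")
  expect_true(all(td$estimate[-1] >= 0))
  gl <- glance(fit)
  expect_gte(gl$logLik, gl$logLik_null)
  expect_s3_class(autoplot(fit, mark = c(knee = 14)), "ggplot")
  cp <- curve_points(fit)
  expect_named(cp, c("grid", "p", "dp", "d2p"))
})
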