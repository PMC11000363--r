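test_that("onset is where the downhill slope reaches its alpha fraction", {
  g <- seq(10, 25, 0.01)
  # flat plateau above 18, linear rise below
  crv <- fitted_curve(g, 0.005 + 0.03 * pmax(18 - g, 0))
  on <- find_onset(crv)
  expect_gte(on, 17.9)
  expect_lte(on, 18.1)
  # constant curve has no onset
  expect_true(is.na(find_onset(fitted_curve(g, rep(0.01, length(g))))))
})

test_that("knee of an injected decreasing logistic is the analytic curvature point", {
  g <- seq(10, 20, 0.01)
  s <- plogis((15 - g) / 1)
  crv <- fitted_curve(g, p = s, dp = -s * (1 - s),
                      d2p = s * (1 - s) * (1 - 2 * s))
  msc <- find_max_slope_change(crv)
  # curvature extrema at 15 +/- ln(2 + sqrt(3)); smaller-x tie-break
  expect_equal(msc$knee, 15 - log(2 + sqrt(3)), tolerance = 0.011)
  expect_equal(sort(msc$alternatives),
               15 + c(-1, 1) * log(2 + sqrt(3)), tolerance = 0.011)
})

test_that("knee finds a single planted slope break", {
  g <- seq(5, 25, 0.01)
  p <- 0.3 - 0.02 * pmin(g, 12) - 0.002 * pmax(g - 12, 0)
  msc <- find_max_slope_change(fitted_curve(g, p))
  expect_equal(msc$knee, 12, tolerance = 0.011)
  expect_error(find_max_slope_change(
    fitted_curve(g, rep(0.05, length(g)))), "no curvature")
})

test_that("Youden cutoff handles separable and indistinguishable classes", {
  y <- youden_cutoff(c(5, 6, 20, 21), c(1, 1, 0, 0))
  expect_equal(y$youden_cutoff, 13)
  expect_equal(y$j, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  # identical classes: J = 0 everywhere, largest candidate returned
  y0 <- youden_cutoff(c(10, 10), c(1, 0))
  expect_equal(y0$j, 0)
  expect_equal(y0$youden_cutoff, 11)
  expect_error(youden_cutoff(1:5, rep(1, 5)),
               class = "rsigcut_one_class_error")
})

test_that("Youden search matches exhaustive brute force", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 200
    died <- rbinom(n, 1, 0.3)
    scores <- rnorm(n, 20 - 5 * died, 4)
    got <- youden_cutoff(scores, died)
    want <- brute_youden(scores, died)
    expect_equal(got$youden_cutoff, want$cutoff)
    expect_equal(got$j, want$j)
  }
})

test_that("Youden J is invariant under strictly monotone score transforms", {
  set.seed(72)
  died <- rbinom(300, 1, 0.25)
  scores <- rnorm(300, 15 - 4 * died, 3)
  a <- youden_cutoff(scores, died)
  b <- youden_cutoff(exp(scores / 5), died)
  expect_equal(a$j, b$j)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  # the transformed cutoff separates the same records
  expect_equal(scores <= a$youden_cutoff,
               exp(scores / 5) <= b$youden_cutoff)
})

test_that("rank AUC equals the trapezoidal ROC area and flips under negation", {
  set.seed(73)
  for (rep in 1:5) {
    died <- rbinom(50, 1, 0.4)
    if (length(unique(died)) < 2) died[1:2] <- c(0, 1)
    scores <- round(rnorm(50, 12 - 3 * died, 3), 1)  # ties likely
    r <- roc_auc(scores, died)
    expect_equal(r$auc, trapezoid_auc(scores, died), tolerance = 1e-12)
    r2 <- roc_auc(-scores, died)
    expect_equal(r$auc, 1 - r2$auc, tolerance = 1e-12)
  }
})

test_that("AUC is 1 under perfect separation and near 0.5 under the null", {
  expect_equal(roc_auc(c(1, 2, 10, 11, 12), c(1, 1, 0, 0, 0))$auc, 1)
  set.seed(74)
  scores <- rnorm(10000)
  died <- rbinom(10000, 1, 0.1)
  a <- roc_auc(scores, died)$auc
  expect_gt(a, 0.48)
  expect_lt(a, 0.52)
})

test_that("AUC and DeLong interval match the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(75)
  died <- rbinom(500, 1, 0.2)
  scores <- rnorm(500, 20 - 4 * died, 5)
  mine <- roc_auc(scores, died)
  ref <- pROC::roc(died, scores, direction = ">", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci_low, ci[1], tolerance = 1e-8)
  expect_equal(mine$ci_high, ci[3], tolerance = 1e-8)
})

test_that("bootstrap CI is seeded, ordered, and brackets the AUC", {
  set.seed(76)
  died <- rbinom(200, 1, 0.3)
  scores <- rnorm(200, 18 - 3 * died, 4)
  b1 <- roc_auc(scores, died, ci = "bootstrap", boot_n = 200,
                boot_seed = 5)
  b2 <- roc_auc(scores, died, ci = "bootstrap", boot_n = 200,
                boot_seed = 5)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_lte(b1$ci_low, b1$auc)
  expect_gte(b1$ci_high, b1$auc)
})

test_that("extract_cutpoints combines curve and threshold analyses", {
  fix <- scored_cohort(8000, 77)
  coh <- fix$cohort
  fit <- fit_shape_spline(coh$rsig, coh$died, spline_spec())
  cp <- extract_cutpoints(fit, coh$rsig, coh$died)
  expect_named(cp, c("onset", "knee", "knee_alternatives",
                     "youden_cutoff", "sensitivity", "specificity", "j"))
  # decreasing curve: onset sits above the knee
  expect_gte(cp$onset, cp$knee)
  expect_gte(cp$j, 0)
  expect_lte(cp$j, 1)
})

test_that("onset of the injected planted curve matches the closed form", {
  # p(x) = floor + range * sigmoid((x0 - x)/w): the relative-slope
  # criterion -p' >= alpha * max(-p') holds for sigma'(z) >= alpha/4,
  # i.e. z in [-z*, z*] with sigma(z*) = (1 - sqrt(1 - alpha))/2,
  # so the onset (largest such x) is x0 - w * qlogis(s_low)
  pars <- risk_curve_params(0.004, 0.5, x0 = 13, w = 2)
  g <- seq(2, 40, 0.01)
  p <- true_mortality(g, pars)
  s <- plogis((pars$x0 - g) / pars$w)
  dp <- -(pars$p_max - pars$p_floor) * s * (1 - s) / pars$w
  crv <- fitted_curve(g, p, dp = dp)
  alpha <- 0.05
  s_low <- (1 - sqrt(1 - alpha)) / 2
  onset_analytic <- pars$x0 - pars$w * qlogis(s_low)
  expect_equal(find_onset(crv, alpha), onset_analytic, tolerance = 0.011)
})
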