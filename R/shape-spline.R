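#' Specification of a shape-restricted regression spline fit
#'
#' Tunable parameters of [fit_shape_spline()]. The defaults realize a
#' standard, reproducible version of shape-restricted binomial spline
#' regression: cubic I-splines with interior knots at quantiles of the
#' distinct scores, a small ridge penalty for identifiability, and an
#' iteratively reweighted least squares outer loop with a
#' nonnegativity-constrained inner solve.
#'
#' @param n_interior_knots number of interior knots (default 5, placed
#'   at quantiles of the distinct scores). The default is deliberately
#'   coarse: the knee extraction reads the second derivative of the
#'   fitted curve, and a knot-dense fit concentrates spurious curvature
#'   at knots near the data-dense shoulder of the curve; five interior
#'   knots bound the knee-recovery error to under one score unit on
#'   cohorts simulated from the planted risk curve (see the methods
#'   vignette).
#' @param degree I-spline degree (default 3, cubic).
#' @param constraint `"decreasing"` forces a nonincreasing fitted
#'   mortality curve; `"unconstrained_shape"` fits a difference of two
#'   monotone components and can bend both ways (used for TBI-like
#'   curves with a high-score mortality rise).
#' @param ridge_lambda ridge penalty weight on the constrained basis
#'   coefficients (>= 0, default 1e-4); stabilizes the nearly collinear
#'   split basis.
#' @param grid_step spacing (score units) of the evaluation grid of the
#'   fitted curve (default 0.01).
#' @param max_iter,tol IRLS iteration cap and relative
#'   penalized-log-likelihood convergence tolerance.
#' @return an object of class `spline_spec`.
#' @export
spline_spec <- function(n_interior_knots = 5L, degree = 3L,
                        constraint = c("decreasing",
                                       "unconstrained_shape"),
                        ridge_lambda = 1e-4, grid_step = 0.01,
                        max_iter = 100L, tol = 1e-8) {
  constraint <- match.arg(constraint)
  if (!is_count(n_interior_knots) || n_interior_knots < 1) {
    stop_config("n_interior_knots", "must be an integer >= 1")
  }
  if (!is.numeric(grid_step) || grid_step <= 0) {
    stop_config("grid_step", "must be > 0")
  }
  if (!is.numeric(ridge_lambda) || ridge_lambda < 0) {
    stop_config("ridge_lambda", "must be >= 0")
  }
  structure(list(n_interior_knots = as.integer(n_interior_knots),
                 degree = as.integer(degree), constraint = constraint,
                 ridge_lambda = ridge_lambda, grid_step = grid_step,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "spline_spec")
}

#' Fit a shape-restricted regression spline of mortality against a score
#'
#' Maximizes the Bernoulli log-likelihood (minus a small ridge penalty)
#' of the model
#' \deqn{\mathrm{logit}\, p(x) = \beta_0 - \sum_j \gamma_j I_j(x)
#'   \quad (\gamma_j \ge 0)}
#' for a nonincreasing curve, or
#' \deqn{\mathrm{logit}\, p(x) = \beta_0 - \sum_j \gamma_j I_j(x)
#'   + \sum_j \delta_j I_j(x) \quad (\gamma, \delta \ge 0)}
#' for an unconstrained shape, where \eqn{I_j} are the monotone
#' I-splines of [ispline_basis()]. The sign constraints are what make
#' the first model monotone: the linear predictor is the intercept
#' minus a nonnegative combination of nondecreasing functions.
#'
#' Fitting alternates iteratively reweighted least squares with a
#' nonnegative least squares inner solve (Lawson-Hanson via
#' [pracma::lsqnonneg()]; the free intercept is split into a positive
#' and a negative part), with step-halving whenever a step fails to
#' improve the penalized log-likelihood.
#'
#' @param x numeric score vector (at least two distinct values).
#' @param y binary outcome (0/1, logical, or "died"/"survived"); both
#'   classes must be present.
#' @param spec a [spline_spec()].
#' @return an object of class `shape_spline` (also `rsig_curve`): a
#'   list with the evaluation `grid`, fitted probabilities `p`, analytic
#'   first/second derivatives `dp`/`d2p`, `knots`, `coefficients`
#'   (intercept plus nonnegative basis weights), `constraint`,
#'   unpenalized `loglik`, the constant-model `loglik_null`,
#'   `converged`, `n_iter`, `n_obs` and the `spec`.
#' @seealso [find_onset()], [find_max_slope_change()], [autoplot.rsig_curve()]
#' @export
fit_shape_spline <- function(x, y, spec = spline_spec()) {
  stopifnot(inherits(spec, "spline_spec"))
  y <- as_died(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2L) abort("need at least 2 distinct x values")
  check_two_classes(y)

  knots <- spline_knots(x, spec$n_interior_knots)
  bas <- ispline_basis(x, knots, spec$degree)
  I <- bas$basis
  X <- if (spec$constraint == "decreasing") -I else cbind(-I, I)
  J <- ncol(X)
  n <- length(y)
  lambda <- spec$ridge_lambda

  pll <- function(b0, theta) {
    eta <- b0 + drop(X %*% theta)
    sum(y * eta - log1p(exp(eta))) - lambda * sum(theta^2) / 2
  }

  b0 <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  theta <- rep(0, J)
  obj <- pll(b0, theta)
  converged <- FALSE
  iter <- 0L
  # ridge rows appended to the weighted LS system; intercept split into
  # +/- parts so lsqnonneg can leave it unconstrained
  ridge_block <- cbind(matrix(0, J, 2L), diag(sqrt(lambda), J))
  for (iter in seq_len(spec$max_iter)) {
    eta <- b0 + drop(X %*% theta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    A <- rbind(cbind(sw, -sw, X * sw), ridge_block)
    d <- c(sw * z, rep(0, J))
    sol <- pracma::lsqnonneg(A, d)$x
    b0_new <- sol[1] - sol[2]
    theta_new <- sol[-(1:2)]
    obj_new <- pll(b0_new, theta_new)
    step <- 1
    while (obj_new < obj && step > 1e-8) {
      step <- step / 2
      b0_new <- b0 + step * ((sol[1] - sol[2]) - b0)
      theta_new <- theta + step * (sol[-(1:2)] - theta)
      obj_new <- pll(b0_new, theta_new)
    }
    done <- abs(obj_new - obj) <= spec$tol * (abs(obj) + 1)
    b0 <- b0_new
    theta <- theta_new
    obj <- obj_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("shape-restricted spline fit did not converge; result returned with converged = FALSE")
  }

  grid <- seq(min(x), max(x), by = spec$grid_step)
  if (tail(grid, 1) < max(x)) grid <- c(grid, max(x))
  gb <- ispline_basis(grid, knots, spec$degree)
  gX0 <- if (spec$constraint == "decreasing") -gb$basis else
    cbind(-gb$basis, gb$basis)
  gX1 <- if (spec$constraint == "decreasing") -gb$d1 else
    cbind(-gb$d1, gb$d1)
  gX2 <- if (spec$constraint == "decreasing") -gb$d2 else
    cbind(-gb$d2, gb$d2)
  eta_g <- b0 + drop(gX0 %*% theta)
  deta <- drop(gX1 %*% theta)
  d2eta <- drop(gX2 %*% theta)
  p <- plogis(eta_g)
  dp <- deta * p * (1 - p)
  d2p <- d2eta * p * (1 - p) + deta^2 * p * (1 - p) * (1 - 2 * p)

  eta_fit <- b0 + drop(X %*% theta)
  loglik <- sum(y * eta_fit - log1p(exp(eta_fit)))
  p_null <- mean(y)
  loglik_null <- sum(y * log(p_null) + (1 - y) * log(1 - p_null))

  coef_names <- if (spec$constraint == "decreasing") {
    paste0("gamma", seq_len(J))
  } else {
    c(paste0("gamma", seq_len(J / 2)), paste0("delta", seq_len(J / 2)))
  }
  structure(
    list(grid = grid, p = p, dp = dp, d2p = d2p, knots = knots,
         coefficients = c(intercept = b0, setNames(theta, coef_names)),
         constraint = spec$constraint, loglik = loglik,
         loglik_null = loglik_null, converged = converged,
         n_iter = iter, n_obs = n, spec = spec),
    class = c("shape_spline", "rsig_curve")
  )
}

#' Construct a fitted curve object from explicit grid values
#'
#' Wraps an externally supplied probability curve (analytic or
#' otherwise) in the same container that [fit_shape_spline()] returns,
#' so the cutpoint extractors can be applied to it. Missing derivatives
#' are filled in by central finite differences.
#'
#' @param grid score grid (strictly increasing, at least 3 points).
#' @param p probabilities on the grid.
#' @param dp,d2p optional first/second derivatives on the grid.
#' @return an object of class `fitted_curve` / `rsig_curve`.
#' @export
#' @examples
#' g <- seq(10, 20, 0.01)
#' crv <- fitted_curve(g, plogis((15 - g) / 1))
fitted_curve <- function(grid, p, dp = NULL, d2p = NULL) {
  stopifnot(length(grid) == length(p), length(grid) >= 3L,
            !is.unsorted(grid, strictly = TRUE))
  h <- diff(grid)
  if (is.null(dp)) {
    dp <- c(diff(p[1:2]) / h[1],
            (p[-(1:2)] - p[seq_len(length(p) - 2)]) /
              (grid[-(1:2)] - grid[seq_len(length(grid) - 2)]),
            diff(p[length(p) - 1:0]) / h[length(h)])
  }
  if (is.null(d2p)) {
    d2p <- c(0,
             diff(diff(p) / h) / ((h[-1] + h[-length(h)]) / 2),
             0)
  }
  structure(list(grid = grid, p = p, dp = dp, d2p = d2p),
            class = c("fitted_curve", "rsig_curve"))
}

#' @export
print.shape_spline <- function(x, ...) {
  cat("Shape-restricted regression spline (", x$constraint, ")\n",
      sep = "")
  cat(sprintf("  n = %d, %d basis functions, logLik %.2f (null %.2f)\n",
              x$n_obs, length(x$coefficients) - 1L, x$loglik,
              x$loglik_null))
  cat(sprintf("  converged: %s after %d IRLS iterations\n",
              x$converged, x$n_iter))
  cat(sprintf("  grid: [%.2f, %.2f] by %.3g\n", min(x$grid), max(x$grid),
              x$spec$grid_step))
  invisible(x)
}

#' Fitted-curve grid as a tibble
#'
#' @param curve an `rsig_curve` ([fit_shape_spline()] or
#'   [fitted_curve()]).
#' @return tibble with columns `grid`, `p`, `dp`, `d2p`.
#' @export
curve_points <- function(curve) {
  stopifnot(inherits(curve, "rsig_curve"))
  tibble::tibble(grid = curve$grid, p = curve$p, dp = curve$dp,
                 d2p = curve$d2p)
}

#' @rdname curve_points
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @export
write_curve <- function(curve, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    readr::write_csv(curve_points(curve), path_csv)
  }
  if (!is.null(path_json)) {
    meta <- list(knots = curve$knots,
                 coefficients = as.list(curve$coefficients),
                 constraint = curve$constraint,
                 spec = if (!is.null(curve$spec)) unclass(curve$spec))
    jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(curve)
}

#' @export
tidy.shape_spline <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.shape_spline <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, logLik = x$loglik,
                 logLik_null = x$loglik_null,
                 converged = x$converged, n_iter = x$n_iter,
                 constraint = x$constraint,
                 n_knots = length(x$knots))
}

#' Plot a fitted mortality curve
#'
#' @param object an `rsig_curve`.
#' @param mark optional named numeric vector of cutpoints to mark with
#'   vertical lines (e.g. `c(knee = 12.6, youden = 16.5)`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rsig_curve <- function(object, mark = NULL, ...) {
  df <- curve_points(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "rSIG", y = "in-hospital mortality") +
    ggplot2::theme_minimal()
  if (!is.null(mark)) {
    mk <- tibble::tibble(cut = names(mark), x = unname(mark))
    gg <- gg + ggplot2::geom_vline(
      data = mk,
      ggplot2::aes(xintercept = .data$x, colour = .data$cut),
      linetype = "dashed")
  }
  gg
}
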