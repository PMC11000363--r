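#' Monotone I-spline basis with analytic derivatives
#'
#' Builds the I-spline (integrated M-spline) basis on a knot vector.
#' Each column is nondecreasing in `x`, bounded in \[0, 1\], equal to 0
#' at the left boundary knot and 1 at the right. A nonnegative
#' combination of I-splines is therefore a nondecreasing function —
#' the building block of shape-restricted regression.
#'
#' The basis is constructed from B-splines: with B-splines
#' \eqn{B_1,\dots,B_m} of degree `degree` on the augmented knot
#' sequence, the j-th I-spline is the partial sum
#' \eqn{I_j(x) = \sum_{k > j} B_k(x)}, whose derivative telescopes to a
#' single (nonnegative) M-spline term. First and second derivative
#' matrices come from the exact B-spline derivatives, not finite
#' differences.
#'
#' @param x evaluation points. Values outside the boundary knots are
#'   clamped to the boundary with a warning.
#' @param knots full sorted knot vector: left boundary, interior knots,
#'   right boundary.
#' @param degree piecewise-polynomial degree of the I-splines (cubic by
#'   default, so the underlying M-splines are quadratic).
#' @return a list with matrices `basis`, `d1`, `d2`
#'   (length(x) x (interior + degree) each) and the `knots`/`degree`
#'   used.
#' @export
#' @examples
#' b <- ispline_basis(seq(0, 1, 0.1), knots = c(0, 0.5, 1), degree = 1)
#' b$basis  # piecewise-linear ramps
ispline_basis <- function(x, knots, degree = 3L) {
  stopifnot(is.numeric(knots), length(knots) >= 3L, degree >= 1L)
  if (is.unsorted(knots, strictly = FALSE)) abort("knots must be sorted")
  a <- knots[1]
  b <- knots[length(knots)]
  interior <- knots[-c(1, length(knots))]
  if (any(x < a | x > b)) {
    warn("evaluation points outside the boundary knots were clamped")
    x <- pmin(pmax(x, a), b)
  }
  ord <- degree + 1L
  aug <- c(rep(a, ord), interior, rep(b, ord))
  nb <- length(interior) + ord
  des <- function(d) {
    if (d >= ord) {
      # derivative order exceeds the piecewise-polynomial degree
      return(matrix(0, length(x), nb))
    }
    splines::splineDesign(aug, x, ord = ord,
                          derivs = rep(d, length(x)))
  }
  # partial-sum matrix: column j of the I-spline basis sums B-spline
  # columns j+1 .. nb
  S <- outer(seq_len(nb), seq_len(nb - 1L), function(m, j) (m >= j + 1) * 1)
  B0 <- des(0L)
  list(basis = B0 %*% S, d1 = des(1L) %*% S, d2 = des(2L) %*% S,
       knots = knots, degree = as.integer(degree))
}

# interior knots at quantiles of the distinct observed scores
spline_knots <- function(x, n_interior) {
  ux <- sort(unique(x))
  probs <- seq_len(n_interior) / (n_interior + 1)
  interior <- unname(quantile(ux, probs, type = 7))
  interior <- interior[interior > min(ux) & interior < max(ux)]
  interior <- unique(interior)
  c(min(ux), interior, max(ux))
}
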