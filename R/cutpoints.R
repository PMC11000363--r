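#' Onset point: where mortality starts to rise above its plateau
#'
#' Scans the fitted curve from high scores downward and returns the
#' largest grid score at which the downhill slope reaches `alpha` times
#' its maximum over the grid — the point where fitted mortality begins
#' to increase as the score falls, relative to the high-score plateau.
#'
#' @param curve an `rsig_curve` (from [fit_shape_spline()] or
#'   [fitted_curve()]).
#' @param alpha relative slope threshold in (0, 1); default 0.05 of the
#'   peak downhill slope magnitude.
#' @return the onset score, or `NA` if the curve never decreases.
#' @export
find_onset <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "rsig_curve"), alpha > 0, alpha < 1)
  down <- -curve$dp
  m <- max(down)
  if (m <= 0) return(NA_real_)
  max(curve$grid[down >= alpha * m])
}

#' Maximal-slope-change (knee) point of a fitted curve
#'
#' Returns the grid score where the absolute second derivative of the
#' fitted probability curve is largest — the point at which the slope
#' of the mortality curve changes the most. Ties (within a relative
#' tolerance of 1e-8 of the maximum, which also absorbs floating-point
#' noise between analytically equal curvature extrema) are broken
#' toward the smaller score, the clinically conservative side. The top
#' three local maxima of |second derivative| are reported as
#' alternatives.
#'
#' @param curve an `rsig_curve`.
#' @return a list with `knee` (score) and `alternatives` (numeric
#'   vector, up to 3 local-maximum scores ordered by curvature
#'   magnitude).
#' @export
find_max_slope_change <- function(curve) {
  stopifnot(inherits(curve, "rsig_curve"))
  a <- abs(curve$d2p)
  m <- max(a)
  if (m <= 1e-12 * max(1, max(abs(curve$p)))) {
    abort("curve has no curvature", class = "rsigcut_flat_curve_error")
  }
  knee <- min(curve$grid[a >= m * (1 - 1e-8)])
  # interior local maxima of |d2p|
  n <- length(a)
  loc <- which(a[2:(n - 1)] >= a[1:(n - 2)] &
                 a[2:(n - 1)] >= a[3:n]) + 1L
  # collapse runs of equal values to their smallest-x representative
  if (length(loc)) {
    keep <- c(TRUE, diff(loc) > 1L)
    loc <- loc[keep]
    loc <- loc[order(a[loc], decreasing = TRUE)]
  }
  alts <- curve$grid[head(loc, 3L)]
  list(knee = knee, alternatives = alts)
}

# candidate thresholds: midpoints between consecutive distinct scores
# plus one below the minimum and one above the maximum
threshold_candidates <- function(scores) {
  us <- sort(unique(scores))
  if (length(us) == 1L) return(c(us - 1, us + 1))
  c(us[1] - 1, (us[-1] + us[-length(us)]) / 2, us[length(us)] + 1)
}

# sensitivity / specificity at each threshold under the convention
# "positive (predicted death) iff score <= threshold"
sens_spec_at <- function(scores, died, thresholds) {
  sd_ <- sort(scores[died == 1L])
  ss_ <- sort(scores[died == 0L])
  sens <- findInterval(thresholds, sd_) / length(sd_)
  spec <- 1 - findInterval(thresholds, ss_) / length(ss_)
  list(sens = sens, spec = spec)
}

#' Youden-index optimal cutoff
#'
#' Finds the threshold maximizing Youden's J = sensitivity +
#' specificity - 1, under the convention that a score at or below the
#' threshold predicts death (low rSIG is worse). Candidate thresholds
#' are the midpoints between consecutive distinct scores plus one
#' candidate below the minimum and one above the maximum; among tied J
#' values the largest threshold is returned.
#'
#' @param scores numeric score vector.
#' @param died binary outcome (0/1, logical, or "died"/"survived").
#' @return one-row tibble: `youden_cutoff`, `sensitivity`,
#'   `specificity`, `j`.
#' @export
#' @examples
#' youden_cutoff(c(5, 6, 20, 21), c(1, 1, 0, 0))  # perfect split at 13
youden_cutoff <- function(scores, died) {
  died <- as_died(died)
  ok <- !is.na(scores) & !is.na(died)
  scores <- scores[ok]
  died <- died[ok]
  check_two_classes(died)
  cand <- threshold_candidates(scores)
  ss <- sens_spec_at(scores, died, cand)
  j <- ss$sens + ss$spec - 1
  best <- max(j)
  idx <- max(which(j >= best - 1e-12))  # ties -> largest threshold
  tibble::tibble(youden_cutoff = cand[idx], sensitivity = ss$sens[idx],
                 specificity = ss$spec[idx], j = j[idx])
}

#' All cutpoints of a fitted curve plus the Youden cutoff
#'
#' Convenience wrapper combining [find_onset()],
#' [find_max_slope_change()] and [youden_cutoff()] into the one-row
#' cutpoint summary used by the analysis pipeline.
#'
#' @inheritParams find_onset
#' @inheritParams youden_cutoff
#' @return one-row tibble: `onset`, `knee`, `knee_alternatives`
#'   (list column), `youden_cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
extract_cutpoints <- function(curve, scores, died, alpha = 0.05) {
  msc <- find_max_slope_change(curve)
  yc <- youden_cutoff(scores, died)
  tibble::tibble(onset = find_onset(curve, alpha), knee = msc$knee,
                 knee_alternatives = list(msc$alternatives)) |>
    dplyr::bind_cols(yc)
}
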