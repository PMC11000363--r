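#' Under- and over-triage rates at a cutoff
#'
#' Within a stated population, the under-triage rate is the percentage
#' of deaths with a score *above* the cutoff (missed high-risk
#' patients) and the over-triage rate is the percentage of survivors
#' with a score *at or below* it (low-risk patients flagged high-risk),
#' under the positivity convention "score <= cutoff predicts death".
#' The American College of Surgeons field-triage targets — under-triage
#' below 5% and over-triage below 35%, both strict — are flagged per
#' row. By construction under-triage equals 100 x (1 - sensitivity)
#' and over-triage equals 100 x (1 - specificity) at the same cutoff.
#'
#' @param scores numeric score vector.
#' @param died binary outcome (0/1, logical, or "died"/"survived").
#' @param cutoff score threshold.
#' @param population `"all"`, `"rsig_le_20"` (score at or below 20 — a
#'   "20 or less" convention), a logical vector over records, or a
#'   predicate `function(scores)` returning one.
#' @return one-row tibble of class `triage_rates`: `cutoff`,
#'   `population`, `n`, `n_deaths`, `n_survivors`, `under_triage_pct`,
#'   `over_triage_pct`, `meets_acs_under`, `meets_acs_over`.
#' @export
#' @examples
#' triage_rates(c(10, 20, 18, 25), c(1, 1, 0, 0), cutoff = 16.5)
triage_rates <- function(scores, died, cutoff, population = "all") {
  died <- as_died(died)
  ok <- !is.na(scores) & !is.na(died)
  scores <- scores[ok]
  died <- died[ok]
  if (is.character(population) && length(population) == 1L) {
    label <- population
    sel <- switch(population,
      all = rep(TRUE, length(scores)),
      rsig_le_20 = scores <= 20,
      abort(sprintf("unknown population `%s`", population),
            class = "rsigcut_config_error"))
  } else if (is.function(population)) {
    label <- "custom"
    sel <- population(scores)
  } else {
    label <- "custom"
    sel <- population[ok]
  }
  stopifnot(is.logical(sel), length(sel) == length(scores))
  s <- scores[sel]
  d <- died[sel]
  if (sum(d == 1L) == 0L || sum(d == 0L) == 0L) {
    abort(sprintf(
      "population `%s` at cutoff %s has an empty stratum (%d deaths, %d survivors)",
      label, format(cutoff), sum(d == 1L), sum(d == 0L)),
      class = "rsigcut_empty_stratum_error")
  }
  under <- 100 * mean(s[d == 1L] > cutoff)
  over <- 100 * mean(s[d == 0L] <= cutoff)
  out <- tibble::tibble(
    cutoff = cutoff, population = label, n = length(s),
    n_deaths = sum(d == 1L), n_survivors = sum(d == 0L),
    under_triage_pct = under, over_triage_pct = over,
    meets_acs_under = under < 5, meets_acs_over = over < 35)
  class(out) <- c("triage_rates", class(out))
  out
}

#' Triage-rate table across cutoffs and populations
#'
#' Evaluates [triage_rates()] on the cross of several cutoffs (e.g. the
#' knee, Youden and onset points) and populations, producing the
#' cutoff-evaluation table of the analysis report.
#'
#' @inheritParams triage_rates
#' @param cutoffs named numeric vector of cutoffs.
#' @param populations character vector of population labels understood
#'   by [triage_rates()].
#' @return a tibble with one row per population x cutoff, with a
#'   `cutoff_name` column.
#' @export
triage_table <- function(scores, died, cutoffs,
                         populations = c("all", "rsig_le_20")) {
  if (is.null(names(cutoffs))) {
    names(cutoffs) <- paste0("cutoff", seq_along(cutoffs))
  }
  purrr::map_dfr(populations, function(pop) {
    purrr::map_dfr(names(cutoffs), function(nm) {
      dplyr::mutate(
        triage_rates(scores, died, cutoffs[[nm]], pop),
        cutoff_name = nm, .before = 1)
    })
  })
}
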