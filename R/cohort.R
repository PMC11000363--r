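#' Blank physiologically implausible vital signs
#'
#' Registry cleaning rule: systolic blood pressure below 30 mmHg or
#' above 300 mmHg, and heart rate above 200 beats/min, are treated as
#' missing. The boundaries themselves (SBP 30, SBP 300, HR 200) are
#' retained — the rule is a strict inequality. All other fields pass
#' through unchanged, and the operation is idempotent.
#'
#' @param data a registry data frame with numeric `sbp` and `hr`
#'   columns.
#' @return the same data frame as a tibble with implausible `sbp`/`hr`
#'   set to `NA`.
#' @export
#' @examples
#' clean_vitals(data.frame(sbp = c(25, 120, 301), hr = c(80, 210, 90)))
clean_vitals <- function(data) {
  stopifnot(all(c("sbp", "hr") %in% names(data)))
  dplyr::mutate(
    tibble::as_tibble(data),
    sbp = replace(.data$sbp, !is.na(.data$sbp) &
                    (.data$sbp < 30 | .data$sbp > 300), NA),
    hr = replace(.data$hr, !is.na(.data$hr) & .data$hr > 200, NA)
  )
}

#' Flow-diagram bookkeeping
#'
#' Constructs the exclusion accounting of a two-stage cohort build:
#' eligibility exclusions first, then missing-data exclusions, with
#' `final = total - excluded_eligibility - excluded_missing` enforced.
#'
#' @param total number of records screened.
#' @param excluded_eligibility records failing any eligibility rule.
#' @param excluded_missing eligible records missing an essential
#'   variable.
#' @return a one-row tibble of class `flow_counts` with columns `total`,
#'   `excluded_eligibility`, `excluded_missing`, `final`.
#' @export
#' @examples
#' flow_counts(2600299, 2197091, 84702)
flow_counts <- function(total, excluded_eligibility, excluded_missing) {
  stopifnot(is_count(total), is_count(excluded_eligibility),
            is_count(excluded_missing))
  final <- total - excluded_eligibility - excluded_missing
  if (final < 0) abort("flow counts imply a negative final cohort")
  out <- tibble::tibble(total = total,
                        excluded_eligibility = excluded_eligibility,
                        excluded_missing = excluded_missing,
                        final = final)
  class(out) <- c("flow_counts", class(out))
  out
}

#' Apply cohort inclusion and exclusion rules with flow accounting
#'
#' Keeps adult (age >= 18) acute-trauma records arriving within 6 hours
#' of injury (`time_to_ed` <= 360 min, boundary inclusive) via the
#' emergency medical system, with a traumatic mechanism and a verifiable
#' in-hospital outcome (survived or died), and with none of the
#' essential variables (SBP, HR, GCS, EMR-ISS, outcome) missing.
#'
#' Exclusions are counted in two stages mirroring a study flow diagram:
#' a record failing any *eligibility* rule (age, arrival time, transport
#' mode, mechanism, transferred-out or dead-on-arrival outcome) counts
#' once as an eligibility exclusion even if it also has missing
#' essentials; only eligible records missing an essential variable count
#' as missing-data exclusions. A missing outcome counts as a
#' missing-data exclusion (an unverifiable treatment result), not an
#' eligibility failure.
#'
#' @param data a cleaned registry data frame (see [clean_vitals()]).
#' @return a list with elements `cohort` (the kept tibble) and `flow`
#'   (a [flow_counts()] row).
#' @export
apply_inclusion <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n == 0L) {
    return(list(cohort = data, flow = flow_counts(0, 0, 0)))
  }
  outcome_known <- !is.na(data$outcome)
  eligible <- !is.na(data$age) & data$age >= 18 &
    !is.na(data$time_to_ed) & data$time_to_ed <= 360 &
    !is.na(data$transport) & data$transport == "ems" &
    !is.na(data$mechanism) & data$mechanism != "nontraumatic" &
    (!outcome_known | data$outcome %in% c("survived", "died"))
  complete <- !is.na(data$sbp) & !is.na(data$hr) & !is.na(data$gcs) &
    !is.na(data$emr_iss) & outcome_known
  keep <- eligible & complete
  flow <- flow_counts(n, sum(!eligible), sum(eligible & !complete))
  list(cohort = data[keep, , drop = FALSE], flow = flow)
}

#' Compare group characteristics (study-population table)
#'
#' Summarizes variables by outcome group the way clinical cohort tables
#' do: continuous variables as median (25th, 75th percentile) compared
#' with the Mann-Whitney U test (tie-corrected normal approximation, no
#' continuity correction); categorical variables as count (%) compared
#' with Pearson's chi-square test without continuity correction
#' (df = categories - 1). A variable constant across all groups gets
#' p-value 1 and a `constant` flag with a warning.
#'
#' @param data a cohort data frame.
#' @param group unquoted name of the grouping column (e.g. `outcome`).
#' @param variables character vector of column names to summarize.
#'   Numeric columns are treated as continuous, everything else
#'   (character, factor, logical) as categorical.
#' @return a long tibble with one row per variable x level x group:
#'   columns `variable`, `type`, `level`, `group`, `n`, `pct` (percent
#'   within group, half-away-from-zero rounded to 1 decimal in
#'   `pct_label`), `median`, `q1`, `q3`, `p_value`, `test`, `constant`.
#' @export
summarize_groups <- function(data, group, variables) {
  data <- tibble::as_tibble(data)
  gq <- rlang::enquo(group)
  g <- rlang::eval_tidy(gq, data)
  if (is.null(g)) abort("grouping column not found")
  g <- as.character(g)
  keep <- !is.na(g)
  data <- data[keep, , drop = FALSE]
  g <- g[keep]
  if (length(unique(g)) < 2L) {
    abort("need at least 2 non-empty groups")
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    abort(paste("variables not in data:",
                paste(missing_vars, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      summarize_continuous(v, x, g)
    } else {
      summarize_categorical(v, x, g)
    }
  })
}

summarize_continuous <- function(v, x, g) {
  ok <- !is.na(x)
  xs <- split(x[ok], g[ok])
  constant <- length(unique(x[ok])) <= 1L
  if (constant) {
    warn(sprintf("variable `%s` is constant; p-value set to 1", v))
    p <- 1
  } else if (length(xs) == 2L) {
    p <- suppressWarnings(
      wilcox.test(xs[[1]], xs[[2]], exact = FALSE, correct = FALSE)$p.value)
  } else {
    p <- stats::kruskal.test(x[ok], factor(g[ok]))$p.value
  }
  purrr::map_dfr(names(xs), function(grp) {
    q <- quantile(xs[[grp]], c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(variable = v, type = "continuous", level = NA_character_,
                   group = grp, n = length(xs[[grp]]), pct = NA_real_,
                   pct_label = NA_real_,
                   median = q[2], q1 = q[1], q3 = q[3],
                   p_value = p,
                   test = if (length(xs) == 2L) "mann-whitney" else
                     "kruskal-wallis",
                   constant = constant)
  })
}

summarize_categorical <- function(v, x, g) {
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  x <- as.character(x)
  ok <- !is.na(x)
  tab <- table(x[ok], g[ok])
  constant <- nrow(tab) <= 1L
  if (constant) {
    warn(sprintf("variable `%s` is constant; p-value set to 1", v))
    p <- 1
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  groups <- colnames(tab)
  purrr::map_dfr(groups, function(grp) {
    counts <- tab[, grp]
    pct <- 100 * counts / sum(counts)
    tibble::tibble(variable = v, type = "categorical",
                   level = rownames(tab), group = grp,
                   n = as.integer(counts), pct = as.numeric(pct),
                   pct_label = round_half_up(as.numeric(pct), 1),
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   p_value = p, test = "chi-square", constant = constant)
  })
}

#' Export flow counts or a group summary as JSON
#'
#' @param x a [flow_counts()] row or [summarize_groups()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
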