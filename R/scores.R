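#' Reverse shock index multiplied by GCS
#'
#' rSIG = (SBP / HR) x GCS: the reverse shock index (systolic blood
#' pressure over heart rate) weighted by the Glasgow Coma Scale. Low
#' values indicate worse physiology — hypotension, tachycardia, or
#' depressed consciousness all pull the score down. The score is never
#' rounded internally.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param hr heart rate, beats/min.
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @return numeric vector of rSIG values; `NA` where any input is
#'   missing or `hr` is zero.
#' @export
#' @examples
#' compute_rsig(120, 80, 15)  # 22.5
compute_rsig <- function(sbp, hr, gcs) {
  if (any(!is.na(gcs) & (gcs < 3 | gcs > 15))) {
    warn("GCS values outside [3, 15] encountered")
  }
  out <- ifelse(!is.na(hr) & hr == 0, NA_real_, (sbp / hr) * gcs)
  as.numeric(out)
}

#' Add shock indices and rSIG columns to a cohort
#'
#' Appends `si` (HR/SBP), `rsi` (SBP/HR) and `rsig` ((SBP/HR) x GCS).
#'
#' @param data cohort data frame with `sbp`, `hr`, `gcs`.
#' @return the tibble with three added columns.
#' @export
add_scores <- function(data) {
  stopifnot(all(c("sbp", "hr", "gcs") %in% names(data)))
  dplyr::mutate(
    tibble::as_tibble(data),
    si = ifelse(!is.na(.data$sbp) & .data$sbp == 0, NA_real_,
                .data$hr / .data$sbp),
    rsi = ifelse(!is.na(.data$hr) & .data$hr == 0, NA_real_,
                 .data$sbp / .data$hr),
    rsig = compute_rsig(.data$sbp, .data$hr, .data$gcs)
  )
}

parse_codes <- function(codes) {
  if (is.list(codes)) {
    lapply(codes, function(x) x[!is.na(x) & nzchar(x)])
  } else {
    out <- strsplit(ifelse(is.na(codes), "", codes), ";", fixed = TRUE)
    lapply(out, function(x) trimws(x[nzchar(trimws(x))]))
  }
}

#' Assign TBI, severity, and sensitivity-analysis subgroups
#'
#' TBI is flagged when any diagnosis code starts with `S06`
#' (intracranial injury); severe trauma when EMR-ISS >= 25. The
#' three-way sensitivity subgroup is `isolated_tbi` (S06 and no other
#' S/T-chapter injury code), `tbi_plus` (S06 plus at least one other
#' injury code), `severe_non_tbi` (no S06 but severe), else `other`.
#' "Isolated" is operationalized as the absence of any non-S06 injury
#' code from the S or T ICD-10 chapters; the pattern is configurable
#' via `injury_pattern`.
#'
#' @param data cohort data frame with a `codes` column
#'   (semicolon-separated string or list column) and `emr_iss`.
#' @param injury_pattern regex identifying injury codes counted as
#'   concomitant injuries (default: S or T chapter).
#' @return the tibble with logical `tbi`, `severe` and character
#'   `subgroup3` columns added.
#' @export
#' @examples
#' assign_subgroups(data.frame(codes = c("S06.5", "S06.5;S32.1", "S32.1"),
#'                             emr_iss = c(10, 30, 25)))
assign_subgroups <- function(data, injury_pattern = "^[ST]") {
  stopifnot(all(c("codes", "emr_iss") %in% names(data)))
  code_list <- parse_codes(data$codes)
  tbi <- vapply(code_list, function(x) any(startsWith(x, "S06")),
                logical(1))
  concomitant <- vapply(code_list, function(x) {
    any(grepl(injury_pattern, x) & !startsWith(x, "S06"))
  }, logical(1))
  severe <- !is.na(data$emr_iss) & data$emr_iss >= 25
  subgroup3 <- dplyr::case_when(
    tbi & !concomitant ~ "isolated_tbi",
    tbi & concomitant ~ "tbi_plus",
    !tbi & severe ~ "severe_non_tbi",
    TRUE ~ "other"
  )
  dplyr::mutate(tibble::as_tibble(data), tbi = tbi, severe = severe,
                subgroup3 = subgroup3)
}

# rows of `data` belonging to a named analysis subgroup
subgroup_filter <- function(data, subgroup) {
  switch(subgroup,
    all = rep(TRUE, nrow(data)),
    tbi = data$tbi,
    non_tbi = !data$tbi,
    isolated_tbi = data$subgroup3 == "isolated_tbi",
    tbi_plus = data$subgroup3 == "tbi_plus",
    severe_non_tbi = data$subgroup3 == "severe_non_tbi",
    abort(sprintf("unknown subgroup `%s`", subgroup),
          class = "rsigcut_config_error")
  )
}
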