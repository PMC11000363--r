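#' Analysis configuration for the end-to-end pipeline
#'
#' @param subgroups subgroups to analyze, drawn from `all`, `tbi`,
#'   `non_tbi`, `isolated_tbi`, `tbi_plus`, `severe_non_tbi`.
#' @param spline a [spline_spec()] used for every subgroup; the
#'   constraint is chosen per subgroup (see Details) unless
#'   `constraints` overrides it.
#' @param constraints optional named character vector mapping subgroup
#'   to `"decreasing"` or `"unconstrained_shape"`.
#' @param onset_alpha relative slope threshold for [find_onset()].
#' @param triage_populations populations for [triage_table()].
#' @param table1_variables variables for the study-population summary.
#' @param or_variables variables for the odds-ratio table.
#' @param seed integer seed recorded in provenance (and used when the
#'   input is a [synthetic_config()] without one).
#'
#' @details TBI-containing subgroups (`tbi`, `isolated_tbi`,
#'   `tbi_plus`) default to the `unconstrained_shape` fit, since their
#'   mortality can rise again at high rSIG (Cushing-reflex
#'   physiology); all others default to the `decreasing` constraint.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(subgroups = c("all", "tbi", "non_tbi",
                                          "isolated_tbi", "tbi_plus",
                                          "severe_non_tbi"),
                            spline = spline_spec(),
                            constraints = NULL,
                            onset_alpha = 0.05,
                            triage_populations = c("all", "rsig_le_20"),
                            table1_variables = c("time_to_ed", "age",
                                                 "sex", "tbi",
                                                 "mechanism", "sbp",
                                                 "hr", "gcs",
                                                 "emr_iss", "rsig"),
                            or_variables = c("time_to_ed", "sex", "age",
                                             "mechanism", "emr_iss",
                                             "rsig"),
                            seed = 1L) {
  known <- c("all", "tbi", "non_tbi", "isolated_tbi", "tbi_plus",
             "severe_non_tbi")
  bad <- setdiff(subgroups, known)
  if (length(bad)) {
    stop_config("subgroups", paste("unknown subgroup(s):",
                                   paste(bad, collapse = ", ")))
  }
  if (!inherits(spline, "spline_spec")) {
    stop_config("spline", "must be a spline_spec object")
  }
  default_constraint <- function(sg) {
    if (sg %in% c("tbi", "isolated_tbi", "tbi_plus")) {
      "unconstrained_shape"
    } else "decreasing"
  }
  cons <- setNames(vapply(subgroups, default_constraint, character(1)),
                   subgroups)
  if (!is.null(constraints)) {
    bad <- setdiff(names(constraints), known)
    if (length(bad)) {
      stop_config("constraints", paste("unknown subgroup(s):",
                                       paste(bad, collapse = ", ")))
    }
    cons[names(constraints)] <- constraints
  }
  structure(list(subgroups = subgroups, spline = spline,
                 constraints = cons, onset_alpha = onset_alpha,
                 triage_populations = triage_populations,
                 table1_variables = table1_variables,
                 or_variables = or_variables,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e)),
          class = "rsigcut_stage_error", parent = e)
  })
}

#' Run the full rSIG cutoff analysis end-to-end
#'
#' Clean -> filter -> score -> fit -> cutpoints -> triage -> regression
#' -> report, for the whole cohort and each configured subgroup. The
#' run is deterministic given the input and seed.
#'
#' @param input a registry data frame of raw records, a path to a
#'   records CSV, a [synthetic_config()] (a registry is generated), or
#'   an `rsig_registry`.
#' @param config an [analysis_config()].
#' @return an object of class `rsig_report`: list with `flow`,
#'   `table1`, `table2`, `curves`, `cutpoints`, `roc`, `triage` (each a
#'   mapping subgroup -> result or a combined tibble) and `provenance`
#'   (config hash, seed, package version, n at each stage).
#' @export
#' @examples
#' \donttest{
#' rep <- run_analysis(synthetic_config(n = 4000, seed = 2),
#'                     analysis_config(subgroups = c("all", "tbi")))
#' rep$cutpoints
#' }
run_analysis <- function(input, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  records <- stage("input", {
    if (inherits(input, "synthetic_config")) {
      generate_registry(input)$records
    } else if (inherits(input, "rsig_registry")) {
      input$records
    } else if (is.character(input) && length(input) == 1L) {
      read_registry(input)
    } else if (is.data.frame(input)) {
      tibble::as_tibble(input)
    } else {
      abort("input must be a data frame, CSV path, synthetic_config or rsig_registry")
    }
  })

  cleaned <- stage("clean_vitals", clean_vitals(records))
  inc <- stage("apply_inclusion", apply_inclusion(cleaned))
  cohort <- stage("score", {
    out <- assign_subgroups(add_scores(inc$cohort))
    out[!is.na(out$rsig), , drop = FALSE]
  })
  cohort$died <- as_died(cohort$outcome)

  table1 <- stage("table1", summarize_groups(
    cohort, outcome, intersect(config$table1_variables, names(cohort))))
  table2 <- stage("table2", build_or_table(
    cohort, config$or_variables, died = died))

  per_subgroup <- purrr::map(setNames(config$subgroups,
                                      config$subgroups), function(sg) {
    sel <- subgroup_filter(cohort, sg)
    dat <- cohort[sel, , drop = FALSE]
    stage(paste0("subgroup_", sg), {
      if (sum(dat$died == 1L) == 0L || sum(dat$died == 0L) == 0L) {
        abort(sprintf("subgroup %s has a single outcome class (n = %d)",
                      sg, nrow(dat)))
      }
      sp <- config$spline
      sp$constraint <- config$constraints[[sg]]
      curve <- fit_shape_spline(dat$rsig, dat$died, sp)
      cut <- extract_cutpoints(curve, dat$rsig, dat$died,
                               alpha = config$onset_alpha)
      roc <- roc_auc(dat$rsig, dat$died)
      cuts <- c(knee = cut$knee, youden = cut$youden_cutoff)
      if (!is.na(cut$onset)) cuts <- c(cuts, onset = cut$onset)
      tri <- triage_table(dat$rsig, dat$died, cuts,
                          config$triage_populations)
      list(curve = curve, cutpoints = cut, roc = roc, triage = tri,
           n = nrow(dat))
    })
  })

  cutpoints <- purrr::map_dfr(names(per_subgroup), function(sg) {
    dplyr::mutate(per_subgroup[[sg]]$cutpoints, subgroup = sg,
                  .before = 1)
  })
  triage <- purrr::map_dfr(names(per_subgroup), function(sg) {
    dplyr::mutate(per_subgroup[[sg]]$triage, subgroup = sg, .before = 1)
  })
  roc_glance <- purrr::map_dfr(names(per_subgroup), function(sg) {
    dplyr::mutate(glance(per_subgroup[[sg]]$roc), subgroup = sg,
                  .before = 1)
  })

  structure(
    list(flow = inc$flow, table1 = table1, table2 = table2,
         curves = purrr::map(per_subgroup, "curve"),
         cutpoints = cutpoints,
         roc = purrr::map(per_subgroup, "roc"),
         roc_summary = roc_glance,
         triage = triage,
         cohort_n = nrow(cohort),
         provenance = list(
           config_hash = rlang::hash(config),
           seed = config$seed,
           package_version = as.character(packageVersion("rsigcut")))),
    class = "rsig_report"
  )
}

#' @export
print.rsig_report <- function(x, ...) {
  cat("rSIG cutoff analysis report\n")
  cat(sprintf("  cohort: %d of %d screened records\n", x$cohort_n,
              x$flow$total))
  cat("  cutpoints by subgroup:\n")
  df <- x$cutpoints
  for (i in seq_len(nrow(df))) {
    cat(sprintf("    %-15s onset %6s  knee %6.2f  youden %6.2f (sens %.3f, spec %.3f)\n",
                df$subgroup[i],
                ifelse(is.na(df$onset[i]), "-",
                       sprintf("%.2f", df$onset[i])),
                df$knee[i], df$youden_cutoff[i], df$sensitivity[i],
                df$specificity[i]))
  }
  cat("  AUC by subgroup:\n")
  rs <- x$roc_summary
  for (i in seq_len(nrow(rs))) {
    cat(sprintf("    %-15s %.3f (%.3f-%.3f)\n", rs$subgroup[i],
                rs$auc[i], rs$ci_low[i], rs$ci_high[i]))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (flow, cutpoints, triage, ROC summaries,
#' provenance), CSVs for the summary tables and each subgroup curve,
#' and optionally curve/ROC plots.
#'
#' @param report an `rsig_report` from [run_analysis()].
#' @param outdir output directory (created if needed).
#' @param plots write PDF plots of curves and ROC panels?
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir, plots = FALSE) {
  stopifnot(inherits(report, "rsig_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    flow = as.list(report$flow),
    cutpoints = dplyr::select(report$cutpoints, -"knee_alternatives"),
    roc = report$roc_summary,
    triage = report$triage,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  readr::write_csv(report$table1, file.path(outdir, "table1.csv"),
                   na = "")
  readr::write_csv(report$table2, file.path(outdir, "table2.csv"),
                   na = "")
  readr::write_csv(report$triage, file.path(outdir, "triage.csv"),
                   na = "")
  for (sg in names(report$curves)) {
    readr::write_csv(curve_points(report$curves[[sg]]),
                     file.path(outdir, paste0("curve_", sg, ".csv")))
  }
  if (plots) {
    grDevices::pdf(file.path(outdir, "curves.pdf"), width = 7,
                   height = 5)
    for (sg in names(report$curves)) {
      cp <- report$cutpoints[report$cutpoints$subgroup == sg, ]
      mk <- c(knee = cp$knee, youden = cp$youden_cutoff)
      print(autoplot(report$curves[[sg]], mark = mk) +
              ggplot2::ggtitle(sg))
      print(autoplot(report$roc[[sg]]) + ggplot2::ggtitle(sg))
    }
    grDevices::dev.off()
  }
  invisible(outdir)
}
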