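#' Binary logistic regression with separation diagnostics
#'
#' Maximum-likelihood logistic fit of death on a covariate table
#' (delegated to [stats::glm()], whose iteratively reweighted least
#' squares converges to the tolerance given). Wald standard errors come
#' from the inverse observed information. Quasi-complete or complete
#' separation — diverging coefficients with fitted probabilities
#' pinned at 0/1 — aborts with a diagnostic rather than returning a
#' meaningless fit.
#'
#' @param design data frame of covariates (numeric or factor columns);
#'   column names become term names.
#' @param died binary outcome (0/1, logical, or "died"/"survived").
#' @param tol IRLS convergence tolerance (default 1e-10).
#' @return an object of class `rsig_logit`: list with `coefficients`,
#'   `se`, `vcov`, `loglik`, `converged`, `n_obs`, and the underlying
#'   `glm` fit.
#' @export
#' @examples
#' fit <- fit_logistic(data.frame(x = rep(0:1, c(100, 100))),
#'                     rep(c(0, 1, 0, 1), c(90, 10, 80, 20)))
#' exp(coef(fit)["x"])  # 2x2 odds ratio (10*90)/(10*80) style
fit_logistic <- function(design, died, tol = 1e-10) {
  died <- as_died(died)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(died))
  ok <- if (ncol(design)) complete.cases(design) & !is.na(died) else
    !is.na(died)
  design <- design[ok, , drop = FALSE]
  died <- died[ok]
  check_two_classes(died)
  dat <- cbind(design, .died = died)
  fml <- if (ncol(design)) .died ~ . else .died ~ 1
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial(),
        control = list(epsilon = tol, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (separation && any(abs(cf) > 15, na.rm = TRUE)) {
    abort(paste0(
      "separation detected: coefficient(s) diverging (max |coef| = ",
      format(max(abs(cf), na.rm = TRUE), digits = 4),
      "); fit aborted"), class = "rsigcut_separation_error")
  }
  if (any(is.na(cf))) {
    abort("design matrix is rank deficient (perfectly collinear columns)")
  }
  vc <- vcov(fit)
  structure(
    list(coefficients = cf, se = sqrt(diag(vc)), vcov = vc,
         loglik = as.numeric(logLik(fit)), converged = fit$converged,
         n_obs = length(died), fit = fit),
    class = "rsig_logit"
  )
}

#' @export
coef.rsig_logit <- function(object, ...) object$coefficients

#' @export
print.rsig_logit <- function(x, ...) {
  cat(sprintf("Logistic regression: %d obs, logLik %.2f\n", x$n_obs,
              x$loglik))
  print(round(cbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
tidy.rsig_logit <- function(x, conf_level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  se <- x$se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std_error = unname(se),
                 statistic = unname(est / se),
                 p_value = 2 * stats::pnorm(-abs(unname(est / se))),
                 or = exp(unname(est)),
                 ci_low = exp(unname(est - zq * se)),
                 ci_high = exp(unname(est + zq * se)))
}

#' @export
glance.rsig_logit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, logLik = x$loglik,
                 converged = x$converged)
}

# variables admissible in the mortality odds-ratio table; the vital
# signs and GCS are refused because they are already reflected in rSIG
.or_allowed <- c("time_to_ed", "sex", "age", "mechanism", "emr_iss",
                 "rsig")
.or_banned <- c("sbp", "hr", "gcs", "si", "rsi", "dbp")

#' Univariable and multivariable odds-ratio table for mortality
#'
#' Fits one univariable logistic regression of death per requested
#' variable, screens variables at univariable p < 0.05 (likelihood-
#' ratio test for the variable as a whole), and fits one joint
#' multivariable model on the variables that pass. Odds ratios are
#' exp(coefficient) with Wald 95% confidence intervals
#' exp(coef +/- 1.96 se). Trauma mechanism is coded as dummies against
#' the traffic-accident reference, whose row carries OR 1 and no CI.
#' SBP, HR and GCS (and derived shock indices) are refused: they are
#' the components of rSIG and may not enter alongside it.
#'
#' @param data cohort data frame containing the variables and a death
#'   indicator.
#' @param variables character vector drawn from `time_to_ed`, `sex`,
#'   `age`, `mechanism`, `emr_iss`, `rsig`.
#' @param died unquoted name of the outcome column (default `died`;
#'   0/1, logical, or "died"/"survived" — the `outcome` column works).
#' @param screen_alpha univariable significance level gating entry to
#'   the multivariable model (default 0.05).
#' @return a tibble of class `or_table`: `variable`, `level`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `analysis`
#'   ("univariable"/"multivariable"), plus a `screened_in` flag on
#'   univariable rows.
#' @export
build_or_table <- function(data, variables = .or_allowed, died = died,
                           screen_alpha = 0.05) {
  data <- tibble::as_tibble(data)
  banned <- intersect(tolower(variables), .or_banned)
  if (length(banned)) {
    abort(paste0("variable(s) ", paste(banned, collapse = ", "),
                 " are components of rSIG and are excluded from the ",
                 "regression by design"),
          class = "rsigcut_banned_variable_error")
  }
  unknown <- setdiff(variables, .or_allowed)
  if (length(unknown)) {
    abort(paste("unsupported variable(s):",
                paste(unknown, collapse = ", ")))
  }
  y <- as_died(rlang::eval_tidy(rlang::enquo(died), data))
  if (is.null(y)) abort("outcome column not found")

  prep <- function(v) {
    x <- data[[v]]
    if (v == "mechanism") {
      x <- factor(x, levels = c("traffic", "fall", "blunt",
                                "penetrating", "other"))
    } else if (v == "sex") {
      x <- factor(x, levels = c("female", "male"))
    }
    x
  }

  uni <- purrr::map(variables, function(v) {
    df <- data.frame(x = prep(v))
    names(df) <- v
    fit <- fit_logistic(df, y)
    # variable-level screen: likelihood-ratio test against the null
    lrt_p <- stats::pchisq(
      2 * (fit$loglik - null_loglik(y[complete.cases(df)])),
      df = length(fit$coefficients) - 1L, lower.tail = FALSE)
    list(fit = fit, p = lrt_p, variable = v)
  })
  selected <- purrr::map_chr(uni, "variable")[
    purrr::map_dbl(uni, "p") < screen_alpha]

  uni_rows <- purrr::map_dfr(uni, function(u) {
    or_rows(u$fit, u$variable, "univariable") |>
      dplyr::mutate(screened_in = u$p < screen_alpha)
  })

  multi_rows <- NULL
  if (length(selected) >= 1L) {
    df <- as.data.frame(purrr::map(setNames(selected, selected), prep))
    fit <- fit_logistic(df, y)
    multi_rows <- purrr::map_dfr(selected, or_rows, fit = fit,
                                 analysis = "multivariable") |>
      dplyr::mutate(screened_in = NA)
  }
  out <- dplyr::bind_rows(uni_rows, multi_rows)
  class(out) <- c("or_table", class(out))
  out
}

null_loglik <- function(y) {
  p <- mean(y)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

or_rows <- function(fit, variable, analysis) {
  td <- tidy(fit)
  x <- fit$fit$model[[variable]]
  if (is.factor(x)) {
    levs <- levels(x)
    ref <- tibble::tibble(variable = variable, level = levs[1],
                          or = 1, ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, analysis = analysis)
    rows <- td[td$term %in% paste0(variable, levs[-1]), ]
    body <- tibble::tibble(variable = variable,
                           level = sub(paste0("^", variable), "",
                                       rows$term),
                           or = rows$or, ci_low = rows$ci_low,
                           ci_high = rows$ci_high,
                           p_value = rows$p_value, analysis = analysis)
    dplyr::bind_rows(ref, body)
  } else {
    rows <- td[td$term == variable, ]
    tibble::tibble(variable = variable, level = NA_character_,
                   or = rows$or, ci_low = rows$ci_low,
                   ci_high = rows$ci_high, p_value = rows$p_value,
                   analysis = analysis)
  }
}
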