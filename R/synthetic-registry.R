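#' Parameters of a planted mortality-risk curve
#'
#' Defines the ground-truth relationship between the rSIG score and the
#' probability of in-hospital death used by the synthetic registry
#' generator. The curve is a decreasing logistic ramp from `p_max` (as
#' rSIG approaches 0) down to `p_floor` (at high rSIG), optionally with a
#' Gaussian bump at high scores that emulates the excess mortality seen
#' in traumatic brain injury at rSIG above 25 (Cushing-reflex
#' physiology: hypertension plus bradycardia inflates rSIG in severe
#' TBI).
#'
#' @param p_floor baseline death probability at high rSIG, in (0, 1).
#' @param p_max death probability as rSIG approaches 0; must exceed
#'   `p_floor`.
#' @param x0 logistic midpoint on the rSIG scale (the planted "knee"
#'   region).
#' @param w logistic width in rSIG units; larger is shallower.
#' @param bump_height amplitude of the extra high-rSIG mortality bump
#'   (TBI records only); 0 disables it.
#' @param bump_center,bump_width center and width (rSIG units) of the
#'   Gaussian bump.
#' @return an object of class `risk_curve_params`.
#' @seealso [true_mortality()], [synthetic_config()]
#' @export
#' @examples
#' risk_curve_params(p_floor = 0.004, p_max = 0.5, x0 = 13, w = 2)
risk_curve_params <- function(p_floor, p_max, x0, w,
                              bump_height = 0, bump_center = 30,
                              bump_width = 3) {
  if (!is_prob(p_floor) || p_floor <= 0) {
    stop_config("p_floor", "must be a probability in (0, 1]")
  }
  if (!is_prob(p_max) || p_max <= p_floor) {
    stop_config("p_max", "must be a probability with p_floor < p_max <= 1")
  }
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    stop_config("w", "must be a positive scalar")
  }
  if (!is.numeric(bump_height) || bump_height < 0) {
    stop_config("bump_height", "must be >= 0")
  }
  if (!is.numeric(bump_width) || bump_width <= 0) {
    stop_config("bump_width", "must be > 0")
  }
  structure(
    list(p_floor = p_floor, p_max = p_max, x0 = x0, w = w,
         bump_height = bump_height, bump_center = bump_center,
         bump_width = bump_width),
    class = "risk_curve_params"
  )
}

#' True death probability at a given rSIG value
#'
#' Evaluates the planted risk curve:
#' \deqn{p(x) = p_{floor} + (p_{max} - p_{floor})\,
#'   \sigma\!\left(\frac{x_0 - x}{w}\right) +
#'   [tbi]\; h \exp\!\left(-\frac{(x - c)^2}{2 s^2}\right)}
#' where \eqn{\sigma} is the logistic function and the bump term
#' (height \eqn{h}, center \eqn{c}, width \eqn{s}) applies to TBI
#' records only.
#'
#' @param x rSIG values (non-negative numeric vector).
#' @param params a [risk_curve_params()] object.
#' @param tbi logical scalar or vector: does the bump term apply?
#' @return vector of death probabilities in (0, 1].
#' @export
#' @examples
#' pars <- risk_curve_params(0.004, 0.5, x0 = 13, w = 2)
#' true_mortality(13, pars)   # midpoint: p_floor + half the range
true_mortality <- function(x, params, tbi = FALSE) {
  stopifnot(inherits(params, "risk_curve_params"), all(x >= 0, na.rm = TRUE))
  p <- params$p_floor +
    (params$p_max - params$p_floor) * plogis((params$x0 - x) / params$w)
  bump <- params$bump_height *
    exp(-((x - params$bump_center) / params$bump_width)^2 / 2)
  pmin(p + as.numeric(tbi) * bump, 1)
}

#' Configuration of the synthetic trauma-registry generator
#'
#' Bundles every knob of [generate_registry()]. The defaults emulate a
#' large national emergency-department injury registry: overall
#' in-hospital mortality between 1 and 3 percent, TBI prevalence near
#' 17 percent, male fraction 61.5 percent, the five trauma-mechanism
#' marginals 37.8/37.3/17.4/6.5/1.0 percent (traffic, fall, blunt,
#' penetrating, other), an rSIG distribution centered near 24, and
#' field-level missingness plus out-of-range vital-sign contamination.
#'
#' @param n number of records to generate (>= 1).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @param tbi_prevalence probability a record carries an S06
#'   (intracranial injury) diagnosis code.
#' @param mechanism_probs length-5 probability vector over
#'   traffic/fall/blunt/penetrating/other; must sum to 1.
#' @param male_frac probability of male sex.
#' @param missing_rates named list mapping field name to the probability
#'   that the field is blanked after outcome assignment.
#' @param contamination_rate probability a record receives one
#'   out-of-range vital (SBP in \[301,400\] or \[5,29\], or HR in
#'   \[201,250\]), exercising the registry cleaning rule.
#' @param curve_nontbi,curve_tbi [risk_curve_params()] for the non-TBI
#'   and TBI ground-truth curves.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 50000L,
                             seed = 1L,
                             tbi_prevalence = 0.166,
                             mechanism_probs = c(traffic = 0.378,
                                                 fall = 0.373,
                                                 blunt = 0.174,
                                                 penetrating = 0.065,
                                                 other = 0.010),
                             male_frac = 0.615,
                             missing_rates = list(sbp = 0.02, dbp = 0.04,
                                                  hr = 0.02, rr = 0.03,
                                                  bt = 0.05, gcs = 0.02,
                                                  emr_iss = 0.03),
                             contamination_rate = 0.005,
                             curve_nontbi = risk_curve_params(
                               p_floor = 0.004, p_max = 0.5,
                               x0 = 13, w = 2),
                             curve_tbi = risk_curve_params(
                               p_floor = 0.006, p_max = 0.55,
                               x0 = 15, w = 2,
                               bump_height = 0.03, bump_center = 30,
                               bump_width = 3)) {
  if (!is_count(n) || n < 1) stop_config("n", "must be an integer >= 1")
  if (!is_count(abs(seed))) stop_config("seed", "must be an integer")
  if (!is_prob(tbi_prevalence)) stop_config("tbi_prevalence", "must be in [0, 1]")
  if (!is_prob(male_frac)) stop_config("male_frac", "must be in [0, 1]")
  if (length(mechanism_probs) != 5L || any(mechanism_probs < 0) ||
      abs(sum(mechanism_probs) - 1) > 1e-9) {
    stop_config("mechanism_probs",
                "must be 5 non-negative probabilities summing to 1")
  }
  if (!all(vapply(missing_rates, is_prob, logical(1)))) {
    stop_config("missing_rates", "all rates must be probabilities in [0, 1]")
  }
  bad <- setdiff(names(missing_rates),
                 c("sbp", "dbp", "hr", "rr", "bt", "gcs", "emr_iss",
                   "time_to_ed"))
  if (length(bad)) {
    stop_config("missing_rates", paste("unknown field(s):",
                                       paste(bad, collapse = ", ")))
  }
  if (!is_prob(contamination_rate)) {
    stop_config("contamination_rate", "must be in [0, 1]")
  }
  if (!inherits(curve_nontbi, "risk_curve_params")) {
    stop_config("curve_nontbi", "must be a risk_curve_params object")
  }
  if (!inherits(curve_tbi, "risk_curve_params")) {
    stop_config("curve_tbi", "must be a risk_curve_params object")
  }
  names(mechanism_probs) <- c("traffic", "fall", "blunt", "penetrating",
                              "other")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         tbi_prevalence = tbi_prevalence,
         mechanism_probs = mechanism_probs, male_frac = male_frac,
         missing_rates = missing_rates,
         contamination_rate = contamination_rate,
         curve_nontbi = curve_nontbi, curve_tbi = curve_tbi),
    class = "synthetic_config"
  )
}

# Monotone quantile map from the uniform latent severity u to GCS.
# Low u = severe. Band edges chosen so ~96% of records are GCS 15 and
# ~1.2% are GCS < 9, mimicking an all-comers (mostly minor) trauma
# registry with overall mortality in the 1-3% range.
.gcs_breaks <- c(0.002, 0.004, 0.006, 0.008, 0.010, 0.012, 0.015,
                 0.018, 0.022, 0.026, 0.031, 0.038)

latent_to_gcs <- function(u) {
  as.integer(3L + findInterval(u, .gcs_breaks))
}

# Gaussian-copula quantile map: monotone in the latent u conditional on
# the idiosyncratic noise z, with loading rho.
copula_map <- function(u, z, rho, location, scale) {
  location + scale * (rho * qnorm(u) + sqrt(1 - rho^2) * z)
}

#' Generate a synthetic trauma registry with planted ground truth
#'
#' Draws `config$n` records from a single-latent-severity model: a
#' uniform latent `u` per patient (low = severe) maps monotonically to
#' GCS through a fixed quantile table and, through a Gaussian copula, to
#' SBP and HR, so that low `u` implies low rSIG. The in-hospital outcome
#' is Bernoulli in the planted curve [true_mortality()] evaluated at the
#' *true* (pre-contamination) rSIG. EMR-ISS is a monotone noisy
#' transform of severity into \[1, 75\]. Missingness and out-of-range
#' contamination are injected after the outcome is assigned, so cleaning
#' and filtering can be evaluated against known truth. Small fractions
#' of ineligible records (minors, late arrivals, non-EMS transport,
#' non-traumatic mechanism, transferred/dead-on-arrival outcomes) are
#' included so inclusion filtering has work to do.
#'
#' @param config a [synthetic_config()] object.
#' @return a list of class `rsig_registry` with elements
#'   \describe{
#'     \item{records}{tibble, one row per patient: `id`, `age`, `sex`,
#'       `time_to_ed`, `mechanism`, `sbp`, `dbp`, `hr`, `rr`, `bt`,
#'       `gcs`, `codes` (semicolon-separated ICD-10-like strings),
#'       `emr_iss`, `transport`, `outcome`.}
#'     \item{truth}{tibble with `id`, `u`, `rsig_true`, `tbi`,
#'       `p_death`, `died` — the ground-truth oracle.}
#'     \item{config}{the generating config.}
#'   }
#' @export
#' @examples
#' reg <- generate_registry(synthetic_config(n = 500, seed = 7))
#' mean(reg$truth$died)
generate_registry <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_config("config", "must be a synthetic_config object")
  }
  withr::with_seed(config$seed, generate_registry_impl(config))
}

generate_registry_impl <- function(config) {
  n <- config$n
  u <- runif(n)

  gcs <- latent_to_gcs(u)
  sbp <- round(copula_map(u, rnorm(n), rho = 0.35, location = 136,
                          scale = 18))
  sbp <- pmin(pmax(sbp, 40), 250)
  hr <- round(copula_map(1 - u, rnorm(n), rho = 0.35, location = 85,
                         scale = 10))
  hr <- pmin(pmax(hr, 40), 180)
  dbp <- round(0.6 * sbp + rnorm(n, 0, 6))
  rr <- pmin(pmax(round(rnorm(n, 20, 2)), 8), 40)
  bt <- round(rnorm(n, 36.5, 0.4), 1)

  # EMR-ISS: monotone noisy transform of severity (1 - u) into [1, 75];
  # the power sharpens the upper tail so EMR-ISS >= 25 marks a ~25%
  # severe stratum.  No claim of clinical realism.
  v <- pnorm(copula_map(1 - u, rnorm(n), rho = 0.85, location = 0,
                        scale = 1))
  emr_iss <- pmin(pmax(as.integer(round(1 + 74 * v^4)), 1L), 75L)

  rsig_true <- (sbp / hr) * gcs
  tbi <- runif(n) < config$tbi_prevalence
  p_death <- ifelse(tbi,
                    true_mortality(rsig_true, config$curve_tbi, tbi = TRUE),
                    true_mortality(rsig_true, config$curve_nontbi,
                                   tbi = FALSE))
  died <- rbinom(n, 1L, p_death)

  # demographics and logistics (internal marginals, see vignette)
  age_v <- pnorm(copula_map(1 - u, rnorm(n), rho = 0.25, location = 0,
                            scale = 1))
  age <- as.integer(round(18 + 62 * age_v^0.9))
  minors <- runif(n) < 0.01
  age[minors] <- sample(16:17, sum(minors), replace = TRUE)
  sex <- ifelse(runif(n) < config$male_frac, "male", "female")
  time_to_ed <- round(rlnorm(n, log(41), 0.55))
  late <- runif(n) < 0.01
  time_to_ed[late] <- round(runif(sum(late), 361, 720))
  transport <- ifelse(runif(n) < 0.97, "ems", "other")
  mechanism <- sample(names(config$mechanism_probs), n, replace = TRUE,
                      prob = config$mechanism_probs)
  mechanism[runif(n) < 0.02] <- "nontraumatic"

  codes <- make_codes(n, tbi)

  outcome <- ifelse(died == 1L, "died", "survived")
  unknown <- runif(n) < 0.015
  outcome[unknown] <- "transferred_unknown"
  doa <- runif(n) < 0.002
  outcome[doa] <- "dead_on_arrival"

  records <- tibble::tibble(
    id = seq_len(n), age = age, sex = sex, time_to_ed = time_to_ed,
    mechanism = mechanism, sbp = as.numeric(sbp), dbp = as.numeric(dbp),
    hr = as.numeric(hr), rr = as.numeric(rr), bt = bt,
    gcs = as.integer(gcs), codes = codes, emr_iss = emr_iss,
    transport = transport, outcome = outcome
  )

  # contamination then missingness, both post-outcome
  records <- contaminate_vitals(records, config$contamination_rate)
  records <- inject_missing(records, config$missing_rates)

  truth <- tibble::tibble(id = seq_len(n), u = u, rsig_true = rsig_true,
                          tbi = tbi, p_death = p_death, died = died)
  structure(list(records = records, truth = truth, config = config),
            class = "rsig_registry")
}

# diagnosis-code strings: S06.x for TBI, optionally plus a concomitant
# non-S06 injury code; non-TBI records get 1-2 non-S06 codes
.other_codes <- c("S32.1", "S72.0", "S22.3", "S36.0", "S42.2", "T07")

make_codes <- function(n, tbi) {
  s06 <- paste0("S06.", sample(0:9, n, replace = TRUE))
  extra <- sample(.other_codes, n, replace = TRUE)
  extra2 <- sample(.other_codes, n, replace = TRUE)
  has_extra <- runif(n) < 0.5
  has_second <- runif(n) < 0.3
  out <- character(n)
  out[tbi] <- ifelse(has_extra[tbi], paste(s06[tbi], extra[tbi], sep = ";"),
                     s06[tbi])
  out[!tbi] <- ifelse(has_second[!tbi],
                      paste(extra[!tbi], extra2[!tbi], sep = ";"),
                      extra[!tbi])
  out
}

contaminate_vitals <- function(records, rate) {
  if (rate <= 0) return(records)
  n <- nrow(records)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(records)
  mode <- sample(1:3, length(hit), replace = TRUE)
  sbp_hi <- hit[mode == 1]
  sbp_lo <- hit[mode == 2]
  hr_hi <- hit[mode == 3]
  records$sbp[sbp_hi] <- sample(301:400, length(sbp_hi), replace = TRUE)
  records$sbp[sbp_lo] <- sample(5:29, length(sbp_lo), replace = TRUE)
  records$hr[hr_hi] <- sample(201:250, length(hr_hi), replace = TRUE)
  records
}

inject_missing <- function(records, rates) {
  for (field in names(rates)) {
    r <- rates[[field]]
    if (r > 0) {
      records[[field]][runif(nrow(records)) < r] <- NA
    }
  }
  records
}

#' Write / read a synthetic registry as CSV
#'
#' `write_registry()` writes `records.csv`, `truth.csv` and
#' `config.yaml` into `dir`; `read_registry()` reads a registry records
#' CSV back in ("" and "NA" are missing-value tokens).
#'
#' @param registry an `rsig_registry` from [generate_registry()].
#' @param dir output directory (created if needed).
#' @param path path of a records CSV.
#' @return `write_registry()` returns `dir` invisibly; `read_registry()`
#'   returns a tibble of records.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "rsig_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(registry$records, file.path(dir, "records.csv"),
                   na = "")
  readr::write_csv(registry$truth, file.path(dir, "truth.csv"), na = "")
  cfg <- registry$config
  cfg_plain <- list(
    n = cfg$n, seed = cfg$seed, tbi_prevalence = cfg$tbi_prevalence,
    mechanism_probs = as.list(cfg$mechanism_probs),
    male_frac = cfg$male_frac, missing_rates = cfg$missing_rates,
    contamination_rate = cfg$contamination_rate,
    curve_nontbi = unclass(cfg$curve_nontbi),
    curve_tbi = unclass(cfg$curve_tbi)
  )
  yaml::write_yaml(cfg_plain, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}
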