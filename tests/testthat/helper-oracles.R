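# independent oracles and shared fixtures

# exhaustive Youden search: plain loops, no shared code with the package
brute_youden <- function(scores, died) {
  us <- sort(unique(scores))
  cand <- c(us[1] - 1, us[length(us)] + 1)
  if (length(us) > 1) {
    cand <- c(cand, (us[-1] + us[-length(us)]) / 2)
  }
  cand <- sort(cand)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    sens <- mean(scores[died == 1] <= t)
    spec <- mean(scores[died == 0] > t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && t > best_t)) {
      best_j <- j
      best_t <- t
    }
  }
  list(cutoff = best_t, j = best_j)
}

# trapezoidal ROC area, built from scratch (positivity: score <= t)
trapezoid_auc <- function(scores, died) {
  ts <- sort(unique(scores))
  tpr <- c(0, vapply(ts, function(t) mean(scores[died == 1] <= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(ts, function(t) mean(scores[died == 0] <= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# population-optimal Youden threshold by numerical integration of the
# true risk model over the realized score distribution
pop_opt_threshold <- function(x, p) {
  o <- order(x)
  x <- x[o]
  p <- p[o]
  Fd <- cumsum(p) / sum(p)
  Fs <- cumsum(1 - p) / sum(1 - p)
  i <- which.max(Fd - Fs)
  if (i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

# cleaned, filtered, scored cohort from the generator
scored_cohort <- function(n, seed, config = synthetic_config(n = n, seed = seed)) {
  reg <- generate_registry(config)
  inc <- apply_inclusion(clean_vitals(reg$records))
  coh <- assign_subgroups(add_scores(inc$cohort))
  coh <- coh[!is.na(coh$rsig), , drop = FALSE]
  coh$died <- as.integer(coh$outcome == "died")
  list(cohort = coh, registry = reg)
}

# the large parameter-recovery cohort, built once per test run
.acc_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.acc_cache$fix)) {
    .acc_cache$fix <- scored_cohort(50000, 20240408)
  }
  .acc_cache$fix
}
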