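test_that("vital-sign cleaning blanks out-of-range values, keeps boundaries", {
  d <- data.frame(sbp = c(25, 29, 30, 120, 300, 301, NA),
                  hr = c(80, 200, 201, 210, 90, NA, 100))
  cl <- clean_vitals(d)
  expect_equal(cl$sbp, c(NA, NA, 30, 120, 300, NA, NA))
  expect_equal(cl$hr, c(80, 200, NA, NA, 90, NA, 100))
  # idempotent
  expect_identical(clean_vitals(cl), cl)
})

test_that("flow counts enforce the conservation identity", {
  fc <- flow_counts(2600299, 2197091, 84702)
  expect_equal(fc$final, 2600299 - 2197091 - 84702)
  expect_error(flow_counts(10, 8, 5), "negative")
})

base_record <- function(...) {
  defaults <- list(age = 40, sex = "male", time_to_ed = 30,
                   mechanism = "traffic", sbp = 120, dbp = 70, hr = 80,
                   rr = 18, bt = 36.5, gcs = 15L, codes = "S32.1",
                   emr_iss = 9L, transport = "ems", outcome = "survived")
  mods <- list(...)
  defaults[names(mods)] <- mods
  tibble::as_tibble(defaults)
}

test_that("inclusion rules exclude with two-stage accounting", {
  rows <- dplyr::bind_rows(
    base_record(),                               # kept
    base_record(age = 17),                       # eligibility
    base_record(time_to_ed = 361),               # eligibility
    base_record(time_to_ed = 360),               # kept (boundary)
    base_record(transport = "other"),            # eligibility
    base_record(mechanism = "nontraumatic"),     # eligibility
    base_record(outcome = "transferred_unknown"),# eligibility
    base_record(outcome = "dead_on_arrival"),    # eligibility
    base_record(gcs = NA),                       # missing
    base_record(emr_iss = NA),                   # missing
    base_record(outcome = NA),                   # missing (unverifiable)
    base_record(age = 17, gcs = NA)              # eligibility (counted once)
  )
  inc <- apply_inclusion(rows)
  expect_equal(inc$flow$total, 12)
  expect_equal(inc$flow$excluded_eligibility, 7)
  expect_equal(inc$flow$excluded_missing, 3)
  expect_equal(inc$flow$final, 2)
  expect_equal(nrow(inc$cohort), 2)
})

test_that("empty input yields an empty cohort with zero counts", {
  inc <- apply_inclusion(base_record()[0, ])
  expect_equal(nrow(inc$cohort), 0)
  expect_equal(inc$flow$total, 0)
  expect_equal(inc$flow$final, 0)
})

test_that("flow conservation holds on generated registries", {
  for (s in c(21, 22, 23)) {
    reg <- generate_registry(synthetic_config(n = 3000, seed = s))
    inc <- apply_inclusion(clean_vitals(reg$records))
    f <- inc$flow
    expect_equal(f$final + f$excluded_eligibility + f$excluded_missing,
                 f$total)
    expect_equal(nrow(inc$cohort), f$final)
  }
})

test_that("chi-square in group summaries matches the hand-computed statistic", {
  # 2x2 table: group A 10/90, group B 20/80
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 100),
    x = c(rep(c("yes", "no"), c(10, 90)), rep(c("yes", "no"), c(20, 80))))
  s <- summarize_groups(d, g, "x")
  # brute-force expected counts
  obs <- matrix(c(90, 10, 80, 20), 2)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expected)^2 / expected)
  expect_equal(unique(s$p_value),
               stats::pchisq(stat, df = 1, lower.tail = FALSE))
  # counts and percentages recompute exactly
  expect_equal(s$n[s$group == "a" & s$level == "yes"], 10L)
  expect_equal(s$pct[s$group == "b" & s$level == "yes"], 20)
})

test_that("categorical percentages sum to 100 within each group", {
  coh <- scored_cohort(2000, 31)$cohort
  s <- summarize_groups(coh, outcome, c("mechanism", "sex", "tbi"))
  sums <- dplyr::summarise(
    dplyr::group_by(s, .data$variable, .data$group),
    total = sum(.data$pct))
  expect_true(all(abs(sums$total - 100) < 0.1))
})

test_that("continuous summaries are median (IQR) with Mann-Whitney p", {
  set.seed(14)
  d <- tibble::tibble(g = rep(c("died", "survived"), c(60, 140)),
                      v = c(rnorm(60, 5), rnorm(140, 6)))
  s <- summarize_groups(d, g, "v")
  expect_equal(s$median[s$group == "died"],
               median(d$v[d$g == "died"]))
  expect_equal(s$q1[s$group == "survived"],
               unname(quantile(d$v[d$g == "survived"], 0.25)))
  pw <- wilcox.test(d$v[d$g == "died"], d$v[d$g == "survived"],
                    exact = FALSE, correct = FALSE)$p.value
  expect_equal(unique(s$p_value), pw)
  expect_equal(unique(s$test), "mann-whitney")
})

test_that("identical groups give p near 1 and constants are flagged", {
  half <- tibble::tibble(v = rep(c(1, 2, 3), 20),
                         m = rep(c("x", "y"), 30))
  d <- dplyr::bind_rows(dplyr::mutate(half, g = "a"),
                        dplyr::mutate(half, g = "b"))
  s <- summarize_groups(d, g, c("v", "m"))
  expect_true(all(s$p_value >= 0.999))
  expect_warning(s2 <- summarize_groups(
    dplyr::mutate(d, k = 1), g, "k"), "constant")
  expect_equal(unique(s2$p_value), 1)
  expect_true(all(s2$constant))
})
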