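followup_fixture <- function() {
  data.frame(
    patient_id = 1:5,
    age = c(60, 65, 55, 70, 62), sex = c("male", "female", "male", "male", "female"),
    subgroup = c(1, 2, 1, 2, 1),
    time_censor = c(14, 14, 14, 14, 14),
    time_death = c(5, 8, NA, 3, NA),
    cause_death = c("myocardial_infarction", "cancer", NA, "stroke", NA),
    time_stroke = c(NA, NA, 6, NA, NA))
}

test_that("event coding follows the outcome definitions", {
  rec <- code_events(followup_fixture())
  ov <- rec[rec$outcome == "overall_mortality", ]
  va <- rec[rec$outcome == "vascular_mortality", ]
  st <- rec[rec$outcome == "ischaemic_stroke", ]

  # death by myocardial infarction at 5y: event for both mortality outcomes
  expect_equal(ov$event[ov$patient_id == 1], 1)
  expect_equal(ov$time[ov$patient_id == 1], 5)
  expect_equal(va$event[va$patient_id == 1], 1)
  expect_equal(va$time[va$patient_id == 1], 5)
  # non-vascular death: overall event, vascular censored at the death time
  expect_equal(ov$event[ov$patient_id == 2], 1)
  expect_equal(va$event[va$patient_id == 2], 0)
  expect_equal(va$time[va$patient_id == 2], 8)
  # alive at study end: censored
  expect_equal(ov$event[ov$patient_id == 5], 0)
  expect_equal(ov$time[ov$patient_id == 5], 14)
  # non-fatal stroke: stroke event; still at risk for mortality
  expect_equal(st$event[st$patient_id == 3], 1)
  expect_equal(ov$event[ov$patient_id == 3], 0)

  bad <- followup_fixture()
  bad$time_death[1] <- -2
  expect_error(code_events(bad), "before the MRI")
})

test_that("vascular deaths are a subset of overall deaths in coded data", {
  set.seed(40)
  for (i in 1:5) {
    n <- 60
    died <- runif(n) < 0.4
    fu <- data.frame(
      patient_id = 1:n, age = rnorm(n, 60, 8),
      sex = sample(c("male", "female"), n, TRUE),
      subgroup = sample(1:3, n, TRUE), time_censor = runif(n, 5, 15),
      time_death = ifelse(died, runif(n, 0, 10), NA),
      cause_death = ifelse(died, sample(c(vascular_causes(), "cancer", "copd"),
                                        n, TRUE), NA))
    rec <- code_events(fu)
    ov <- rec[rec$outcome == "overall_mortality", ]
    va <- rec[rec$outcome == "vascular_mortality", ]
    expect_true(all(ov$event[va$event == 1] == 1))
  }
})

test_that("outcome summary computes the vascular share of deaths", {
  rec <- code_events(followup_fixture())
  s <- summarize_outcomes(rec)
  expect_equal(s$n_deaths, 3)
  expect_equal(s$n_vascular, 2)
  expect_equal(s$vascular_share_pct, 100 * 2 / 3)
})

test_that("merged reference design has one indicator per non-reference subgroup", {
  f <- build_reference(rep(1:11, 5), reference = c(1, 2, 3, 7))
  expect_equal(levels(f), c("ref", "4", "5", "6", "8", "9", "10", "11"))
  expect_equal(sum(f == "ref"), 4 * 5)

  f2 <- build_reference(rep(1:2, 4), reference = 1)
  expect_equal(levels(f2), c("ref", "2"))
  expect_error(build_reference(rep(1:3, 3), reference = 1:3), "reference")
  expect_error(build_reference(rep(9, 3), reference = c(1, 2)), "not present")
})

test_that("Cox coefficient matches a partial-likelihood grid-search oracle", {
  fix <- data.frame(
    patient_id = 1:8, outcome = "overall_mortality",
    time = c(1.1, 2.3, 3.1, 4.4, 5.2, 6.7, 7.5, 9.0),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    age = 60, sex = "male", subgroup = c(1, 2, 1, 2, 2, 1, 1, 2))
  hz <- fit_cox(fix, reference = 1, covariates = character())
  x <- as.integer(fix$subgroup == 2)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = fix$time, event = fix$event, x = x)
  beta_oracle <- grid[which.max(ll)]
  expect_equal(log(hz$hr[1]), beta_oracle, tolerance = 1e-3)
})

test_that("the single-covariate Cox score test equals the log-rank statistic", {
  set.seed(41)
  n <- 40
  time <- round(rexp(n, 0.1), 3) + seq_len(n) * 1e-4   # distinct times
  event <- rbinom(n, 1, 0.8)
  grp <- rep(0:1, n / 2)
  fit <- survival::coxph(survival::Surv(time, event) ~ grp)
  sc <- summary(fit)$sctest[["test"]]
  lr <- survival::survdiff(survival::Surv(time, event) ~ grp)$chisq
  expect_equal(sc, lr, tolerance = 1e-6)
})

test_that("hazard ratios are invariant to time-unit rescaling", {
  set.seed(42)
  meta <- data.frame(patient_id = 1:400, age = rnorm(400, 59, 10),
                     sex = sample(c("male", "female"), 400, TRUE),
                     subgroup = rep(1:2, each = 200))
  hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.03),
                    offsets = matrix(c(0, log(2)), 2, 1,
                                     dimnames = list(NULL, "overall_mortality")),
                    horizon = 12, dropout_rate = 0, seed = 9)
  rec <- simulate_survival(meta, hs)
  hz_y <- fit_cox(rec, reference = 1)
  rec_d <- rec
  rec_d$time <- rec_d$time * 365.25
  hz_d <- fit_cox(rec_d, reference = 1)
  expect_equal(hz_y$hr, hz_d$hr, tolerance = 1e-9)
})

test_that("log-hazard bias is small at n = 2000 under the generator truth", {
  set.seed(43)
  lhr <- replicate(60, {
    meta <- data.frame(patient_id = 1:2000, age = rnorm(2000, 59, 10),
                       sex = sample(c("male", "female"), 2000, TRUE),
                       subgroup = rep(1:2, each = 1000))
    hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.015),
                      offsets = matrix(c(0, log(2)), 2, 1,
                                       dimnames = list(NULL, "overall_mortality")),
                      horizon = 15, dropout_rate = 0,
                      seed = sample.int(1e6, 1))
    log(fit_cox(simulate_survival(meta, hs), reference = 1)$hr[1])
  })
  expect_lt(abs(mean(lhr) - log(2)), 0.05)
})

test_that("forest plot exports round-trip and annotates non-estimable rows", {
  est <- structure(data.frame(
    outcome = "overall_mortality", subgroup = c("4", "5"),
    hr = c(1.5, NA), ci_low = c(0.9, NA), ci_high = c(2.4, NA),
    se = c(0.25, NA), n_events = c(12L, 0L), estimable = c(TRUE, FALSE)),
    class = c("hazard_estimates", "data.frame"))
  tmp <- file.path(tempdir(), "forest.png")
  out <- forest_plot(est, file = tmp)
  expect_true(file.exists(tmp))
  tsv <- read.table(sub("png$", "tsv", tmp), header = TRUE, sep = "\t")
  expect_equal(tsv$hr[1], 1.5)
  expect_true(is.na(tsv$hr[2]))
  expect_s3_class(out$plot, "ggplot")
  single <- forest_plot(est[1, ])
  expect_equal(nrow(single$table), 1)
})
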