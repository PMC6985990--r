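test_that("cohort generation is deterministic in spec + seed", {
  a <- simulate_cohort(cohort_spec(seed = 12))
  b <- simulate_cohort(cohort_spec(seed = 12))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_spec(seed = 13))
  expect_false(identical(a$features, c$features))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(dispersion = -1), "positive semi-definite")
  expect_error(cohort_spec(n_patients = 100, sizes = c(50, 40)), "sum")
  sp <- cohort_spec()
  expect_equal(sum(sp$sizes), 1003)
  expect_equal(min(dist(sp$centroids)), 6, tolerance = 1e-9)
  expect_true(all(sp$sizes >= 46 & sp$sizes <= 188))
})

test_that("zero dispersion pins members to their centroid", {
  sp <- cohort_spec(n_patients = 22, n_clusters = 2, dispersion = 0,
                    missing_rates = setNames(rep(0, length(clustering_features())),
                                             clustering_features()),
                    sizes = c(11, 11), seed = 1)
  co <- simulate_cohort(sp)
  x <- as.matrix(co$features[, -1])
  for (g in 1:2) {
    rows <- x[co$meta$subgroup_true == g, ]
    expect_true(all(abs(sweep(rows, 2, sp$centroids[g, ])) < 1e-12))
  }
})

test_that("well-separated two-cluster cohorts are recovered exactly by Ward", {
  sp <- cohort_spec(n_patients = 100, n_clusters = 2, sizes = c(50, 50),
                    dispersion = 1,
                    centroids = rbind(rep(0, 5), c(6, 6, 6, 6, 6) / sqrt(5) * 3),
                    missing_rates = c(), seed = 3)
  co <- simulate_cohort(sp)
  lab <- cut_ward(ward_linkage(as.matrix(co$features[, -1])), 2)
  expect_equal(length(unique(lab[co$meta$subgroup_true == 1])), 1)
  expect_equal(length(unique(lab[co$meta$subgroup_true == 2])), 1)
})

test_that("missingness lands at the declared rates and structural pattern", {
  co <- simulate_cohort(cohort_spec(seed = 17))
  x <- co$features
  expect_equal(mean(is.na(x$fd_dwmh)), 0.385, tolerance = 0.01)
  expect_equal(mean(is.na(x$eccentricity)), 0.385, tolerance = 0.01)
  expect_lt(abs(mean(is.na(x$cbf_norm)) - 0.064), 0.02)
  expect_equal(mean(is.na(x$bpf)), 0)
  # structural: missing deep-WMH shape goes with the lowest deep-WMH burden
  dw <- rowMeans(x[, grep("^dwmh_frac_", names(x))])
  expect_lt(mean(dw[is.na(x$fd_dwmh)]), mean(dw[!is.na(x$fd_dwmh)]))
})

test_that("ages respect the truncation range and subgroup ordering", {
  co <- simulate_cohort(cohort_spec(seed = 19))
  expect_true(all(co$meta$age >= 25 & co$meta$age <= 82))
  mean_ages <- tapply(co$meta$age, co$meta$subgroup_true, mean)
  # planted age shifts rise with the subgroup index (sampling noise allows
  # occasional local inversions, the trend must be strong)
  expect_gt(cor(mean_ages, seq_along(mean_ages)), 0.9)
})

test_that("exponential event times have the planted mean when uncensored", {
  meta <- data.frame(patient_id = 1:4000, age = 59, sex = "female", subgroup = 1)
  hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.2),
                    offsets = matrix(0, 1, 1,
                                     dimnames = list(NULL, "overall_mortality")),
                    age_coef = 0, sex_coef = 0, horizon = 1e6,
                    dropout_rate = 0, seed = 5)
  rec <- simulate_survival(meta, hs)
  expect_equal(mean(rec$event), 1)
  expect_equal(mean(rec$time), 1 / 0.2, tolerance = 0.05)
})

test_that("a vanishing censoring horizon censors everyone at ~0", {
  meta <- data.frame(patient_id = 1:50, age = 59, sex = "male", subgroup = 1)
  hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.01),
                    offsets = matrix(0, 1, 1,
                                     dimnames = list(NULL, "overall_mortality")),
                    age_coef = 0, sex_coef = 0, horizon = 1e-9,
                    dropout_rate = 0, seed = 6)
  rec <- simulate_survival(meta, hs)
  expect_true(all(rec$event == 0))
  expect_true(all(rec$time <= 1e-9))
})

test_that("two exchangeable subgroups have indistinguishable hazards", {
  meta <- data.frame(patient_id = 1:2000, age = rnorm(2000, 59, 10),
                     sex = "male", subgroup = rep(1:2, each = 1000))
  hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.02),
                    offsets = matrix(0, 2, 1,
                                     dimnames = list(NULL, "overall_mortality")),
                    age_coef = 0, sex_coef = 0, horizon = 15,
                    dropout_rate = 0, seed = 7)
  rec <- simulate_survival(meta, hs)
  hz <- fit_cox(rec, reference = 1, covariates = character())
  expect_lt(hz$ci_low[1], 1)
  expect_gt(hz$ci_high[1], 1)
})

test_that("empirical hazard ratio converges to the planted offset difference", {
  meta <- data.frame(patient_id = 1:2000, age = 59, sex = "female",
                     subgroup = rep(1:2, each = 1000))
  hs <- hazard_spec(baseline_rates = c(overall_mortality = 0.02),
                    offsets = matrix(c(0, log(3)), 2, 1,
                                     dimnames = list(NULL, "overall_mortality")),
                    age_coef = 0, sex_coef = 0, horizon = 15,
                    dropout_rate = 0, seed = 8)
  rec <- simulate_survival(meta, hs)
  hz <- fit_cox(rec, reference = 1, covariates = character())
  expect_equal(hz$hr[1], 3, tolerance = 0.1)
})

test_that("negative baseline rates are rejected", {
  expect_error(hazard_spec(baseline_rates = c(overall_mortality = -0.1)),
               "rates")
})
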