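# Hand-built three-patient fixture used across the assembly tests.
fixture_sources <- function() {
  lobes <- lobe_names()
  fractions <- data.frame(patient_id = c("a", "b", "c"),
                          bpf = c(78, 75, 72), wm_frac = c(35, 34, 33),
                          gm_frac = c(40, 38, 36), csf_frac = c(18, 20, 22),
                          ventricle_frac = c(4, 5, 6))
  wmh_lobe <- data.frame(patient_id = c("a", "b", "c"))
  for (l in lobes) {
    wmh_lobe[[paste0("cpwmh_frac_", l)]] <- c(0.1, 0, 0.3)
    wmh_lobe[[paste0("dwmh_frac_", l)]] <- c(0, 0.05, 0.2)
  }
  wmh_lobe$cpwmh_frac_frontal <- c(0.4, 0, 0.3)   # patient a: frontal only
  shape <- data.frame(patient_id = c("a", "b", "c"),
                      solidity = c(0.9, 0.85, 0.7),
                      convexity = c(0.95, 0.9, 0.8),
                      concavity_index = c(0.15, 0.25, 0.5),
                      eccentricity = c(0.3, 0.5, 0.7),
                      fd_cpwmh = c(1.6, 1.8, 2.2), fd_dwmh = c(NA, 1.7, 2.1))
  infarcts <- data.frame(patient_id = c("a", "b", "c"),
                         n_lacunes = c(0, 1, 4), n_cortical_infarcts = c(0, 0, 2),
                         n_subcortical_infarcts = c(0, 1, 1))
  for (l in lobes) {
    infarcts[[paste0("cortical_infarct_", l)]] <- c(0, 0, 1)
    infarcts[[paste0("lacunes_", l)]] <- c(0, 1, 1)
  }
  cbf <- data.frame(patient_id = c("a", "b", "c"), cbf_norm = c(52, 48, 40))
  list(fractions = fractions, wmh_lobe = wmh_lobe, shape = shape,
       infarcts = infarcts, cbf = cbf)
}

test_that("assembly joins sources into the declared column set", {
  src <- fixture_sources()
  tab <- assemble_features(src$fractions, src$wmh_lobe, src$shape,
                           src$infarcts, src$cbf)
  expect_equal(names(tab), c("patient_id", clustering_features()))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cbf_norm, c(52, 48, 40))
  expect_equal(tab$cpwmh_frac_parietal[1], 0.1)

  # a patient missing from one source is an error naming it
  expect_error(assemble_features(src$fractions, src$wmh_lobe[-2, ], src$shape,
                                 src$infarcts, src$cbf), "wmh_lobe")
})

test_that("assembly is permutation-invariant in patient order", {
  src <- fixture_sources()
  tab1 <- assemble_features(src$fractions, src$wmh_lobe, src$shape,
                            src$infarcts, src$cbf)
  src2 <- lapply(src, function(d) d[c(3, 1, 2), , drop = FALSE])
  tab2 <- assemble_features(src2$fractions, src2$wmh_lobe, src2$shape,
                            src2$infarcts, src2$cbf)
  tab2 <- tab2[match(tab1$patient_id, tab2$patient_id), ]
  rownames(tab2) <- NULL
  expect_equal(tab1, tab2)
})

test_that("per-lobe WMH fractions partition the class totals on a phantom", {
  hp <- make_head_phantom(phantom_spec(seed = 9, n_wmh = 4))
  v <- compute_volumes(hp)
  wmh <- hp$labels == hp$dict[["wmh"]]
  vent <- hp$labels == hp$dict[["lateral_ventricles"]]
  dim(wmh) <- dim(vent) <- dim(hp$labels)
  cl <- classify_wmh(wmh, vent, hp$spacing)
  lf <- wmh_lobe_fractions(cl$class_map, hp$lobe_map, hp$spacing, v$icv)
  cp_total <- 100 * sum(cl$class_map == 1L) * prod(hp$spacing) / v$icv
  dw_total <- 100 * sum(cl$class_map == 2L) * prod(hp$spacing) / v$icv
  expect_equal(sum(lf[grep("^cpwmh", names(lf))]), cp_total, tolerance = 1e-9)
  expect_equal(sum(lf[grep("^dwmh", names(lf))]), dw_total, tolerance = 1e-9)
})

test_that("normalization fixes minmax endpoints, standardizes z-columns, inverts", {
  tab <- data.frame(patient_id = sprintf("p%02d", 1:30),
                    a = c(0, 1, 2, runif(27, 0, 2)),
                    b = rnorm(30), cnt = rpois(30, 2) + rep(0:1, 15))
  nm <- normalize_features(tab, methods = c(a = "minmax02", b = "zscore",
                                            cnt = "minmax02"))
  expect_equal(nm$x[1:3, "a"], 2 * (c(0, 1, 2) - min(tab$a)) / diff(range(tab$a)))
  simple <- normalize_features(data.frame(patient_id = 1:3, a = c(0, 1, 2)),
                               methods = c(a = "minmax02"))
  expect_equal(unname(simple$x[, "a"]), c(0, 1, 2))
  expect_equal(mean(nm$x[, "b"]), 0, tolerance = 1e-12)
  expect_equal(sd(nm$x[, "b"]), 1, tolerance = 1e-12)
  expect_true(all(nm$x[, "cnt"] >= 0 & nm$x[, "cnt"] <= 2))

  back <- denormalize_features(nm)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
  expect_equal(back$cnt, as.numeric(tab$cnt), tolerance = 1e-12)

  expect_error(normalize_features(data.frame(patient_id = 1:4, k = rep(1, 4))),
               "'k'")
})

test_that("imputation fills normalized centres and leaves complete data alone", {
  tab <- data.frame(patient_id = 1:20, a = rnorm(20), b = runif(20, 0, 5))
  nm <- normalize_features(tab, methods = c(a = "zscore", b = "minmax02"))
  expect_identical(impute_missing(nm)$x, nm$x)

  tab$a[4] <- NA; tab$b[7] <- NA
  nm2 <- impute_missing(normalize_features(tab,
                                           methods = c(a = "zscore", b = "minmax02")))
  expect_equal(unname(nm2$x[4, "a"]), 0)
  expect_equal(unname(nm2$x[7, "b"]), unname(median(nm2$x[-7, "b"])))
  expect_equal(sum(nm2$imputed$n), 2)

  tab$a[] <- NA
  expect_error(impute_missing(normalize_features(tab,
                              methods = c(a = "zscore", b = "minmax02"))),
               "constant|fully missing")
})

test_that("clustering survives the deep-WMH missingness pattern (ARI >= 0.8)", {
  spec <- cohort_spec(seed = 31)
  co <- simulate_cohort(spec)
  nm <- impute_missing(normalize_features(co$features))
  lab_imp <- cut_ward(ward_linkage(nm), 11)

  spec0 <- cohort_spec(missing_rates = setNames(
    rep(0, length(clustering_features())), clustering_features()), seed = 31)
  co0 <- simulate_cohort(spec0)
  lab0 <- cut_ward(ward_linkage(impute_missing(normalize_features(co0$features))), 11)
  expect_gte(mclust::adjustedRandIndex(lab_imp, lab0), 0.8)
  expect_gte(mclust::adjustedRandIndex(lab_imp, co$meta$subgroup_true), 0.8)
})
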