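#' Default subgroup centroid profiles in normalized feature space
#'
#' Eleven phenotype profiles that qualitatively mirror the published
#' subgroup contrasts: four low-burden groups (differing mildly in
#' parenchymal fraction, white/grey matter and blood flow), two
#' limited-burden groups, a cortical-infarct group, a lacunar group, a
#' small-vessel-disease group (high WMH fractions and fractal dimension,
#' low solidity), a multi-burden group (atrophy plus WMH plus lacunes) and
#' a neurodegenerative group (pronounced atrophy). Profiles are expressed
#' directly in normalized units (SD for Z-scored columns) and rescaled so
#' the minimum pairwise centroid separation equals `separation`.
#'
#' @param separation minimum pairwise Euclidean distance between centroids
#'   in normalized-SD units (default 6).
#' @return 11 x length([clustering_features()]) numeric matrix.
#' @export
subgroup_centroids <- function(separation = 6) {
  cols <- clustering_features()
  k <- 11
  m <- matrix(0, k, length(cols), dimnames = list(NULL, cols))
  set_f <- function(g, what, val) {
    m[g, what] <<- val
  }
  lobes <- lobe_names()
  cp <- paste0("cpwmh_frac_", lobes); dw <- paste0("dwmh_frac_", lobes)
  ci <- paste0("cortical_infarct_", lobes); la <- paste0("lacunes_", lobes)
  # low-burden branch (1, 2, 3, 7)
  set_f(1, c("bpf", "ventricle_frac", "solidity"), c(1.2, -1.0, 0.8))
  set_f(2, c("wm_frac", "solidity", "convexity"), c(1.4, 1.2, 0.8))
  set_f(3, c("gm_frac", "convexity", "bpf"), c(1.4, 1.2, 0.6))
  set_f(7, c("cbf_norm", "csf_frac", "wm_frac"), c(1.6, -0.8, 0.6))
  # limited burden (4, 8)
  set_f(4, c(cp[1], "fd_cpwmh", "csf_frac"), c(1.5, 0.8, 0.6))
  set_f(8, c(dw[2], "eccentricity", "fd_dwmh"), c(1.6, 1.2, 1.0))
  # cortical infarcts (5)
  set_f(5, "n_cortical_infarcts", 2.5)
  set_f(5, ci, rep(1.6, 4))
  # lacunes (6)
  set_f(6, "n_lacunes", 2.5)
  set_f(6, la, rep(1.6, 4))
  set_f(6, "n_subcortical_infarcts", 1.2)
  # prominent CSVD (9)
  set_f(9, cp, rep(1.6, 4)); set_f(9, dw, rep(1.2, 4))
  set_f(9, c("fd_cpwmh", "fd_dwmh", "solidity", "concavity_index", "n_lacunes"),
        c(1.8, 1.6, -1.4, 1.4, 1.0))
  # multi-burden (10)
  set_f(10, c("bpf", "ventricle_frac", "csf_frac"), c(-2.0, 2.0, 1.4))
  set_f(10, cp, rep(2.0, 4)); set_f(10, dw, rep(1.6, 4))
  set_f(10, c("concavity_index", "fd_cpwmh", "fd_dwmh", "solidity", "n_lacunes"),
        c(2.0, 1.8, 1.6, -1.8, 1.4))
  # neurodegenerative (11)
  set_f(11, c("bpf", "ventricle_frac", "csf_frac", "gm_frac", "cbf_norm"),
        c(-2.4, 2.4, 1.8, -1.8, -1.0))
  # Every phenotype also carries a modest signature of its own (one feature
  # bumped per subgroup, cycling through the feature list): subgroups are
  # distinct on more than the dominant burden axes, which keeps the pairwise
  # centroid geometry from degenerating among the low-burden profiles.
  # (signatures avoid the features with substantial missingness, whose
  # imputation would split a subgroup into observed/imputed halves)
  sig_pool <- setdiff(cols, c("eccentricity", "fd_dwmh", "cbf_norm"))
  sig <- sig_pool[((seq_len(k) - 1) * 3) %% length(sig_pool) + 1]
  for (g in seq_len(k)) m[g, sig[g]] <- m[g, sig[g]] + 1.5
  # rescale to the requested minimum pairwise separation
  dmin <- min(dist(m))
  m * (separation / dmin)
}

default_subgroup_sizes <- function() {
  c(188L, 149L, 95L, 90L, 85L, 80L, 75L, 70L, 65L, 60L, 46L)
}

#' Default feature missingness rates
#'
#' Mirrors the published missingness pattern: 38.5% for deep-WMH fractal
#' dimension and eccentricity (patients without deep lesions), 6.4% for
#' blood flow, 0.4% for the remaining shape means.
#' @return named numeric vector of rates between 0 and 1.
#' @export
default_missing_rates <- function() {
  r <- setNames(rep(0, length(clustering_features())), clustering_features())
  r[c("fd_dwmh", "eccentricity")] <- 0.385
  r["cbf_norm"] <- 0.064
  r[c("solidity", "convexity", "concavity_index", "fd_cpwmh")] <- 0.004
  r
}

#' Specification of a synthetic feature-space cohort
#'
#' Cluster centroids live directly in normalized feature units (the
#' published tables give group contrasts, not raw generative
#' distributions). Subgroup sizes default
#' to eleven groups between 46 and 188 patients summing to 1003; ages are
#' Normal(59, 10) truncated to 25--82 years with subgroup-specific shifts
#' so that subgroup numbering by mean age is well defined.
#'
#' @param n_patients cohort size.
#' @param n_clusters number of planted subgroups.
#' @param centroids matrix n_clusters x n_features; default
#'   [subgroup_centroids()] when `n_clusters == 11`.
#' @param sizes cluster sizes summing to `n_patients`.
#' @param dispersion within-subgroup per-feature SD in normalized units
#'   (scalar or vector), must be >= 0. The default 0.5 makes the planted
#'   11-subgroup partition the dominant structure: the phenotype profiles
#'   form three coarse branches (low-burden, infarct-dominated,
#'   atrophy/WMH-dominated), and with substantially larger within-group
#'   noise the validity indices legitimately prefer the three-branch cut
#'   over the planted subgroups.
#' @param missing_rates named per-column missingness rates.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param sex_p proportion of male patients.
#' @param seed integer seed; the cohort is a pure function of spec + seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1003, n_clusters = 11,
                        centroids = NULL, sizes = NULL, dispersion = 0.5,
                        missing_rates = default_missing_rates(),
                        age_mean = 59, age_sd = 10, age_range = c(25, 82),
                        sex_p = 0.75, seed = 1L) {
  stop_if(n_clusters < 1, "n_clusters must be >= 1")
  stop_if(any(dispersion < 0), "dispersion matrix not positive semi-definite")
  if (is.null(centroids)) {
    centroids <- if (n_clusters == 11) subgroup_centroids()
                 else subgroup_centroids()[seq_len(n_clusters), , drop = FALSE]
  }
  if (is.null(sizes)) {
    sizes <- if (n_clusters == 11) default_subgroup_sizes() else {
      base <- rep(n_patients %/% n_clusters, n_clusters)
      base[seq_len(n_patients %% n_clusters)] <- base[seq_len(n_patients %% n_clusters)] + 1L
      base
    }
  }
  stop_if(sum(sizes) != n_patients, "cluster sizes must sum to n_patients")
  stop_if(nrow(centroids) != n_clusters, "one centroid row per cluster required")
  structure(list(n_patients = n_patients, n_clusters = n_clusters,
                 centroids = centroids, sizes = as.integer(sizes),
                 dispersion = dispersion, missing_rates = missing_rates,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 sex_p = sex_p, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a feature-space cohort with planted cluster structure
#'
#' Features are drawn cluster-wise around the spec's centroids with
#' independent Gaussian dispersion, then missingness is injected at the
#' per-column rates. The planted labels are returned for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list: `features` (data frame, `patient_id` + feature columns,
#'   with NAs), `meta` (data frame: `patient_id`, `age`, `sex`,
#'   `subgroup_true`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- ncol(spec$centroids)
  disp <- rep(spec$dispersion, length.out = p)
  g <- rep(seq_len(spec$n_clusters), spec$sizes)
  n <- spec$n_patients
  x <- spec$centroids[g, , drop = FALSE] +
    matrix(rnorm(n * p), n, p) %*% diag(disp, p)
  colnames(x) <- colnames(spec$centroids)
  # Missingness. The deep-WMH shape features are missing for the patients
  # with the least deep-WMH burden (no deep lesions means no deep-lesion
  # shape), so their rate is applied structurally, lowest burden first;
  # the remaining rates are technical dropouts, missing at random.
  rates <- spec$missing_rates
  structural <- intersect(c("fd_dwmh", "eccentricity"), colnames(x))
  dw_cols <- grep("^dwmh_frac_", colnames(x), value = TRUE)
  for (j in colnames(x)) {
    r <- rates[[j]] %||% 0
    if (r <= 0) next
    if (j %in% structural && length(dw_cols) > 0) {
      burden <- rowMeans(x[, dw_cols, drop = FALSE])
      x[rank(burden, ties.method = "first") <= round(r * n), j] <- NA
    } else {
      x[runif(n) < r, j] <- NA
    }
  }
  # ages: subgroup-shifted so mean age increases with the planted label
  shift <- seq(-8, 8, length.out = spec$n_clusters)[g]
  age <- rnorm(n, spec$age_mean + shift, spec$age_sd)
  age <- pmin(pmax(age, spec$age_range[1]), spec$age_range[2])
  sex <- ifelse(runif(n) < spec$sex_p, "male", "female")
  ids <- sprintf("P%04d", seq_len(n))
  list(features = cbind(data.frame(patient_id = ids), as.data.frame(x)),
       meta = data.frame(patient_id = ids, age = age, sex = sex,
                         subgroup_true = g))
}

#' Planted log-hazard offsets mirroring the published subgroup contrasts
#'
#' Subgroups 1, 2, 3 and 7 (the merged low-burden reference) and the two
#' limited-burden groups carry no excess hazard; the infarct, lacunar,
#' small-vessel, multi-burden and neurodegenerative groups carry the
#' hazard-ratio pattern reported for overall mortality, vascular mortality
#' and ischaemic stroke.
#'
#' @return 11 x 3 matrix of log hazard ratios (columns per outcome).
#' @export
default_hazard_offsets <- function() {
  hr <- cbind(
    overall_mortality  = c(1, 1, 1, 1, 1.85, 2.58, 1, 1, 1.72, 4.00, 2.70),
    vascular_mortality = c(1, 1, 1, 1, 4.00, 3.45, 1, 1, 2.31, 8.00, 4.14),
    ischaemic_stroke   = c(1, 1, 1, 1, 4.19, 7.22, 1, 1, 8.54, 10.34, 7.17))
  log(hr)
}

#' Specification of planted survival hazards
#'
#' @param baseline_rates events per person-year in the reference stratum
#'   at the centring age, named per outcome.
#' @param offsets matrix of per-subgroup log-hazard offsets (rows =
#'   subgroups, columns = outcomes).
#' @param age_coef,sex_coef log-hazard per year of age (centred at
#'   `age_center`) and for male sex.
#' @param age_center centring age in years.
#' @param horizon administrative censoring horizon (years).
#' @param dropout_rate independent exponential loss-to-follow-up rate
#'   (per person-year).
#' @param seed integer seed.
#' @return object of class `hazard_spec`.
#' @export
hazard_spec <- function(baseline_rates = c(overall_mortality = 0.008,
                                           vascular_mortality = 0.004,
                                           ischaemic_stroke = 0.0025),
                        offsets = default_hazard_offsets(),
                        age_coef = 0.08, sex_coef = 0.3, age_center = 59,
                        horizon = 15, dropout_rate = 0.005, seed = 1L) {
  stop_if(any(baseline_rates < 0) || dropout_rate < 0, "rates must be >= 0")
  stop_if(horizon <= 0, "horizon must be > 0")
  structure(list(baseline_rates = baseline_rates, offsets = offsets,
                 age_coef = age_coef, sex_coef = sex_coef,
                 age_center = age_center, horizon = horizon,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "hazard_spec")
}

#' Simulate survival records under proportional hazards
#'
#' For each outcome, a latent exponential event time with rate
#' `h0 * exp(offset + age_coef * (age - center) + sex_coef * male)` is
#' drawn per patient and censored at the earlier of the administrative
#' horizon and an independent exponential dropout time. Outcomes are
#' simulated independently (the cause-specific view used by the analysis
#' stage).
#'
#' @param meta data frame with `patient_id`, `age`, `sex` and a subgroup
#'   column (`subgroup` or `subgroup_true`).
#' @param spec a [hazard_spec()].
#' @return data frame of survival records: `patient_id`, `outcome`,
#'   `time` (years), `event` (0/1), `age`, `sex`, `subgroup`.
#' @export
simulate_survival <- function(meta, spec) {
  stopifnot(inherits(spec, "hazard_spec"))
  sub <- meta$subgroup %||% meta$subgroup_true
  stop_if(is.null(sub) || anyNA(sub) || anyNA(meta$age) || anyNA(meta$sex),
          "every patient needs age, sex and subgroup")
  set.seed(spec$seed)
  n <- nrow(meta)
  male <- as.integer(meta$sex == "male")
  censor <- pmin(spec$horizon,
                 if (spec$dropout_rate > 0) rexp(n, spec$dropout_rate) else Inf)
  out <- lapply(names(spec$baseline_rates), function(oc) {
    lp <- spec$offsets[sub, oc] + spec$age_coef * (meta$age - spec$age_center) +
      spec$sex_coef * male
    rate <- spec$baseline_rates[[oc]] * exp(lp)
    t_event <- ifelse(rate > 0, rexp(n) / rate, Inf)
    time <- pmin(t_event, censor)
    data.frame(patient_id = meta$patient_id, outcome = oc, time = time,
               event = as.integer(t_event <= censor), age = meta$age,
               sex = meta$sex, subgroup = sub)
  })
  do.call(rbind, out)
}
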