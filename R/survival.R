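#' Causes of death counted as vascular-related
#'
#' Myocardial infarction, stroke, sudden death, congestive heart failure,
#' rupture of an abdominal aortic aneurysm or another vascular cause.
#' @return character vector of cause codes.
#' @export
vascular_causes <- function() {
  c("myocardial_infarction", "stroke", "sudden_death",
    "congestive_heart_failure", "aaa_rupture", "other_vascular")
}

#' Code follow-up into outcome-specific survival records
#'
#' From one follow-up row per patient, builds the per-outcome records for
#' overall mortality, vascular-related mortality (deaths whose cause is in
#' [vascular_causes()]; other deaths are censored at the death time) and
#' ischaemic stroke (non-fatal strokes leave the patient at risk for the
#' mortality outcomes). Patients without an event are censored at their
#' last contact. Times are years since the MRI scan; an event before the
#' scan date is an error.
#'
#' @param followup data frame with columns `patient_id`, `age`, `sex`,
#'   `subgroup`, `time_censor` (years; last contact / end of follow-up),
#'   and optionally `time_death`, `cause_death`, `time_stroke` (NA when
#'   absent).
#' @return data frame of records: `patient_id`, `outcome`, `time`,
#'   `event`, `age`, `sex`, `subgroup`.
#' @export
code_events <- function(followup) {
  need <- c("patient_id", "age", "sex", "subgroup", "time_censor")
  stop_if(!all(need %in% names(followup)),
          paste("followup must have columns:", paste(need, collapse = ", ")))
  td <- followup$time_death %||% rep(NA_real_, nrow(followup))
  ts <- followup$time_stroke %||% rep(NA_real_, nrow(followup))
  cause <- followup$cause_death %||% rep(NA_character_, nrow(followup))
  stop_if(any(td < 0 | ts < 0 | followup$time_censor < 0, na.rm = TRUE),
          "event before the MRI date")
  base <- followup[, c("patient_id", "age", "sex", "subgroup")]
  mk <- function(outcome, time, event) {
    cbind(data.frame(patient_id = base$patient_id, outcome = outcome,
                     time = time, event = as.integer(event)),
          base[, c("age", "sex", "subgroup")])
  }
  died <- !is.na(td)
  t_mort <- ifelse(died, td, followup$time_censor)
  overall <- mk("overall_mortality", t_mort, died)
  vasc_event <- died & cause %in% vascular_causes()
  vascular <- mk("vascular_mortality", t_mort, vasc_event)
  stroked <- !is.na(ts)
  t_stroke <- ifelse(stroked, ts, pmin(t_mort, followup$time_censor))
  stroke <- mk("ischaemic_stroke", t_stroke, stroked)
  rbind(overall, vascular, stroke)
}

#' Outcome summary counts
#'
#' Deaths, vascular-related deaths (with their percentage share of all
#' deaths), and strokes, from coded survival records.
#'
#' @param records output of [code_events()] or [simulate_survival()].
#' @return list: `n_deaths`, `n_vascular`, `vascular_share_pct`,
#'   `n_strokes`, `n_patients`.
#' @export
summarize_outcomes <- function(records) {
  ev <- function(oc) sum(records$event[records$outcome == oc])
  n_deaths <- ev("overall_mortality")
  n_vascular <- ev("vascular_mortality")
  list(n_patients = length(unique(records$patient_id)),
       n_deaths = n_deaths, n_vascular = n_vascular,
       vascular_share_pct = if (n_deaths > 0) 100 * n_vascular / n_deaths
                            else NA_real_,
       n_strokes = ev("ischaemic_stroke"))
}

#' Merge reference subgroups into one baseline level
#'
#' Builds the subgroup factor used by the Cox model: members of the
#' reference subgroups share one baseline level, every other subgroup
#' keeps its own indicator.
#'
#' @param subgroups vector of subgroup labels.
#' @param reference labels forming the merged reference (default the
#'   low-burden branch 1, 2, 3, 7).
#' @return factor with level `"ref"` first; attribute `"reference"` lists
#'   the merged labels.
#' @export
build_reference <- function(subgroups, reference = c(1, 2, 3, 7)) {
  present <- unique(subgroups)
  stop_if(!any(reference %in% present), "reference subgroups not present")
  stop_if(all(present %in% reference), "every patient is in the reference; no contrasts")
  lev <- c("ref", sort(setdiff(present, reference)))
  f <- factor(ifelse(subgroups %in% reference, "ref", as.character(subgroups)),
              levels = as.character(lev))
  attr(f, "reference") <- intersect(reference, present)
  f
}

#' Cause-specific Cox models per outcome
#'
#' Fits a proportional-hazards model per outcome with the merged-reference
#' subgroup factor and the adjustment covariates, maximizing the partial
#' likelihood with the Efron tie correction (Breslow available). Hazard
#' ratios are `exp(coef)` with normal-approximation 95% CIs. A subgroup
#' without events yields a non-estimable flag rather than a number.
#'
#' @param records survival records (long format; see [code_events()]).
#' @param reference subgroup labels merged into the baseline.
#' @param covariates covariate column names (default age and sex).
#' @param ties `"efron"` or `"breslow"`.
#' @return data frame of class `hazard_estimates`: one row per subgroup x
#'   outcome with `hr`, `ci_low`, `ci_high`, `se`, `n_events`,
#'   `estimable`.
#' @export
fit_cox <- function(records, reference = c(1, 2, 3, 7),
                    covariates = c("age", "sex"), ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  out <- list()
  for (oc in unique(records$outcome)) {
    rec <- records[records$outcome == oc, , drop = FALSE]
    stop_if(sum(rec$event) < 1, sprintf("no events for outcome %s", oc))
    rec$.sub <- build_reference(rec$subgroup, reference)
    rhs <- paste(c(".sub", covariates), collapse = " + ")
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
      data = rec, ties = ties)
    cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
    for (lev in levels(rec$.sub)[-1]) {
      nm <- paste0(".sub", lev)
      n_ev <- sum(rec$event[rec$.sub == lev])
      estimable <- n_ev > 0 && is.finite(cf[[nm]]) && is.finite(se[[nm]]) &&
        se[[nm]] < 50
      out[[length(out) + 1]] <- data.frame(
        outcome = oc, subgroup = lev,
        hr = if (estimable) exp(cf[[nm]]) else NA_real_,
        ci_low = if (estimable) exp(cf[[nm]] - 1.96 * se[[nm]]) else NA_real_,
        ci_high = if (estimable) exp(cf[[nm]] + 1.96 * se[[nm]]) else NA_real_,
        se = if (estimable) se[[nm]] else NA_real_,
        n_events = n_ev, estimable = estimable)
    }
  }
  structure(do.call(rbind, out), class = c("hazard_estimates", "data.frame"))
}

#' Forest plot of subgroup hazard ratios
#'
#' One row per subgroup and outcome on a log-scaled axis with the
#' reference line at HR = 1; non-estimable contrasts are annotated rather
#' than drawn. The underlying numbers round-trip through the returned
#' table.
#'
#' @param estimates a `hazard_estimates` table from [fit_cox()].
#' @param file optional path; when given the plot is written there and the
#'   table next to it as TSV.
#' @return list: `plot` (ggplot object), `table` (the estimates).
#' @export
forest_plot <- function(estimates, file = NULL) {
  stop_if(nrow(estimates) == 0, "no estimates to plot")
  est <- as.data.frame(estimates)
  est$label <- paste0("subgroup ", est$subgroup)
  shown <- est[est$estimable, , drop = FALSE]
  p <- ggplot2::ggplot(shown,
         ggplot2::aes(x = hr, y = label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Hazard ratio (95% CI) vs merged reference", y = NULL) +
    ggplot2::theme_bw()
  if (any(!est$estimable)) {
    p <- p + ggplot2::labs(
      caption = paste("Non-estimable:",
                      paste(est$label[!est$estimable], collapse = ", ")))
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 1.2 + 0.35 * nrow(est))
    write.table(est, sub("\\.[a-z]+$", ".tsv", file), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(plot = p, table = est)
}
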