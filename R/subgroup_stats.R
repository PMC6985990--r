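#' Bonferroni adjustment
#'
#' @param p p-values between 0 and 1.
#' @param m number of comparisons (default `length(p)`).
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stop_if(m < 1, "m must be >= 1")
  pmin(1, m * p)
}

#' Age/sex-adjusted group comparison of a continuous variable (ANCOVA)
#'
#' Fits `value ~ covariates + subgroup` by least squares, tests the
#' subgroup block with the overall F test and reports all pairwise
#' subgroup contrasts (difference, 95% CI, Bonferroni-adjusted p over the
#' number of pairs). Variables with a skewed distribution can be
#' natural-log transformed first; zero-inflated variables are offset by
#' half the smallest positive observed value before the log.
#'
#' @param values numeric outcome.
#' @param groups subgroup labels.
#' @param covariates data frame of adjustment covariates (default: none),
#'   e.g. age and sex.
#' @param log_transform apply the offset natural-log transform first.
#' @return object of class `comparison_result`: test, overall statistic
#'   and p, pairwise contrast table, transform note.
#' @export
ancova_group_test <- function(values, groups, covariates = NULL,
                              log_transform = FALSE) {
  stop_if(!is.numeric(values), "values must be numeric")
  transform <- "none"
  if (log_transform) {
    pos <- values[!is.na(values) & values > 0]
    off <- if (length(pos)) min(pos) / 2 else 0.5
    values <- log(values + off)
    transform <- sprintf("log(x + %.4g)", off)
  }
  groups <- factor(groups)
  small <- names(which(table(groups[!is.na(values)]) < 2))
  if (length(small) > 0) {
    warning(sprintf("subgroups with < 2 observations dropped from contrasts: %s",
                    paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- droplevels(groups[keep])
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  df <- data.frame(.y = values, .g = groups)
  rhs <- ".g"
  if (!is.null(covariates) && ncol(covariates) > 0) {
    df <- cbind(df, covariates)
    rhs <- paste(c(names(covariates), ".g"), collapse = " + ")
    fit0 <- lm(stats::reformulate(names(covariates), ".y"), data = df)
  } else {
    fit0 <- lm(.y ~ 1, data = df)
  }
  fit <- lm(stats::reformulate(rhs, ".y"), data = df)
  an <- anova(fit0, fit)
  overall_f <- an$F[2]
  overall_p <- an$`Pr(>F)`[2]

  # pairwise contrasts from the full fit (treatment coding)
  levs <- levels(df$.g)
  cf <- coef(fit); V <- vcov(fit)
  bname <- function(l) paste0(".g", l)
  eff <- setNames(numeric(length(levs)), levs)
  for (l in levs[-1]) eff[l] <- cf[[bname(l)]]
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- eff[b] - eff[a]
    va <- if (a == levs[1]) 0 else V[bname(a), bname(a)]
    vb <- if (b == levs[1]) 0 else V[bname(b), bname(b)]
    vab <- if (a == levs[1] || b == levs[1]) 0 else V[bname(a), bname(b)]
    se <- sqrt(va + vb - 2 * vab)
    t <- d / se
    p <- 2 * pt(-abs(t), fit$df.residual)
    data.frame(group_a = a, group_b = b, diff = unname(d), se = se,
               ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
               p = p, p_adj = NA_real_)
  })
  contrasts <- do.call(rbind, rows)
  contrasts$p_adj <- bonferroni(contrasts$p, m)
  structure(list(test = "ancova", overall_stat = overall_f,
                 overall_p = overall_p, contrasts = contrasts,
                 covariates = if (is.null(covariates)) character()
                              else names(covariates),
                 transform = transform, n_comparisons = m),
            class = "comparison_result")
}

#' Subgroup association of a discrete feature (multinomial logistic)
#'
#' Multinomial logistic regression with subgroup as the outcome and the
#' feature plus covariates as predictors (so each non-reference subgroup
#' gets an odds ratio versus the reference, matching the published
#' "OR (95% CI)" layout). The overall feature effect is tested with a
#' likelihood-ratio test against the covariate-only model. Perfect
#' separation is flagged and the affected CI reported as unbounded.
#'
#' @param feature discrete/binary predictor.
#' @param groups subgroup labels (outcome).
#' @param covariates optional data frame (age, sex).
#' @param reference reference subgroup label (baseline outcome category).
#' @return `comparison_result` with per-subgroup OR, 95% Wald CI and the
#'   LRT p-value.
#' @export
multinomial_feature_or <- function(feature, groups, covariates = NULL,
                                   reference = NULL) {
  groups <- factor(groups)
  stop_if(length(unique(feature[!is.na(feature)])) < 2, "feature is constant")
  if (!is.null(reference)) {
    stop_if(!reference %in% levels(groups), "reference subgroup not present")
    groups <- stats::relevel(groups, ref = as.character(reference))
  }
  df <- data.frame(.g = groups, .x = feature)
  rhs0 <- "1"
  if (!is.null(covariates) && ncol(covariates) > 0) {
    df <- cbind(df, covariates)
    rhs0 <- paste(names(covariates), collapse = " + ")
  }
  fit0 <- nnet::multinom(stats::reformulate(rhs0, ".g"), data = df,
                         trace = FALSE, maxit = 200)
  fit <- nnet::multinom(stats::reformulate(c(rhs0, ".x"), ".g"), data = df,
                        trace = FALSE, maxit = 200)
  lrt <- fit0$deviance - fit$deviance
  dfree <- length(levels(groups)) - 1
  overall_p <- pchisq(lrt, dfree, lower.tail = FALSE)

  cf <- coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(cf))) {  # two groups: coerce to matrix
    cf <- matrix(cf, 1, dimnames = list(levels(groups)[2], names(coef(fit))))
    se <- matrix(se, 1, dimnames = dimnames(cf))
  }
  beta <- cf[, ".x"]; sdev <- se[, ".x"]
  separated <- !is.finite(sdev) | sdev > 50 | abs(beta) > 20
  or_tab <- data.frame(subgroup = rownames(cf), or = exp(beta), se = sdev,
                       ci_low = exp(beta - 1.96 * sdev),
                       ci_high = exp(beta + 1.96 * sdev),
                       separated = separated, row.names = NULL)
  or_tab$ci_low[separated] <- 0
  or_tab$ci_high[separated] <- Inf
  structure(list(test = "multinomial", overall_stat = lrt,
                 overall_p = overall_p, or = or_tab,
                 reference = levels(groups)[1],
                 covariates = if (is.null(covariates)) character()
                              else names(covariates)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: overall statistic %.3f, p = %.4g\n",
              x$test, x$overall_stat, x$overall_p))
  invisible(x)
}

#' Compare many variables between subgroups
#'
#' Convenience wrapper producing a tidy table over continuous (ANCOVA)
#' and discrete (multinomial) variables, age(/sex)-adjusted and
#' Bonferroni-corrected, mirroring the published between-subgroup
#' comparison layout.
#'
#' @param data data frame holding the variables and covariates.
#' @param groups subgroup labels.
#' @param continuous,discrete character vectors of column names.
#' @param covariates character vector of covariate column names (default
#'   `"age"`).
#' @param log_vars continuous columns to log transform first.
#' @param reference reference subgroup for the odds ratios.
#' @return data frame: variable, test, overall statistic and p.
#' @export
compare_subgroups <- function(data, groups, continuous = character(),
                              discrete = character(), covariates = "age",
                              log_vars = character(), reference = NULL) {
  cov_df <- if (length(covariates)) data[, covariates, drop = FALSE] else NULL
  rows <- list()
  for (v in continuous) {
    r <- ancova_group_test(data[[v]], groups, cov_df, v %in% log_vars)
    rows[[v]] <- data.frame(variable = v, test = "ancova",
                            statistic = r$overall_stat, p = r$overall_p)
  }
  for (v in discrete) {
    r <- multinomial_feature_or(data[[v]], groups, cov_df, reference)
    rows[[v]] <- data.frame(variable = v, test = "multinomial",
                            statistic = r$overall_stat, p = r$overall_p)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p, nrow(out))
  rownames(out) <- NULL
  out
}
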