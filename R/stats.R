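## Cohort-level statistics: association tests for the baseline table,
## paired comparison of zone TSRs, survival analysis and logistic models
## for perineural invasion.  Model fitting is delegated to the survival
## package and stats::glm (the conventional R toolchain for these
## analyses); the chi-square statistic is computed explicitly so the
## continuity-correction convention is pinned down.

new_test_result <- function(statistic, df, p_value, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df,
                   p_value = p_value, method = method), extra),
            class = "tsr_test")
}

#' @export
print.tsr_test <- function(x, ...) {
  cat(sprintf("<tsr_test> %s: statistic %.4g%s, p = %.4g\n", x$method,
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(" (df %g)", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Chi-square association test with the 2x2 continuity correction
#'
#' For 2x2 tables the Yates-corrected statistic
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` is used (the corrected deviation is
#' floored at zero, so p = 1 is attainable exactly); larger tables use
#' the ordinary Pearson statistic with `(r-1)(c-1)` degrees of freedom.
#' This is the convention under which the published baseline-table
#' p-values reproduce exactly.
#'
#' @param table A [contingency_table] (or plain count matrix).
#' @param correct Apply the continuity correction to 2x2 tables
#'   (default `TRUE`).
#' @return A `tsr_test` with method `chi_square_yates` or `chi_square`.
#' @export
chi_square_test <- function(table, correct = TRUE) {
  counts <- if (inherits(table, "contingency_table")) table$counts
            else as.matrix(table)
  if (any(counts < 0)) stop2("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop2("table total must be positive")
  rm <- rowSums(counts); cm <- colSums(counts)
  if (any(rm == 0) || any(cm == 0))
    stop2("zero row or column margin: test undefined")
  expected <- outer(rm, cm) / n
  yates <- correct && all(dim(counts) == 2L)
  dev <- abs(counts - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                  if (yates) "chi_square_yates" else "chi_square")
}

#' Paired t-test between the inner-tumor and ITF TSR of each patient
#'
#' @param x,y Equal-length numeric vectors (n >= 2), typically the
#'   per-patient inner and ITF TSRs.
#' @return A `tsr_test` with the t statistic, df = n - 1, two-sided p,
#'   and the mean difference `mean(x - y)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop2("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop2("need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop2("zero variance of paired differences: t statistic undefined")
  fit <- stats::t.test(x, y, paired = TRUE)
  new_test_result(unname(fit$statistic), unname(fit$parameter),
                  fit$p.value, "paired_t",
                  extra = list(mean_difference = mean(d)))
}

#' Spearman rank correlation
#'
#' @param u,v Equal-length numeric vectors (n >= 3).
#' @return A `tsr_test` with `statistic` = rho and the asymptotic
#'   two-sided p (ties allowed).
#' @export
spearman_association <- function(u, v) {
  if (length(u) != length(v)) stop2("'u' and 'v' must have equal length")
  if (length(u) < 3L) stop2("need at least three observations")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop2("constant input: rank correlation undefined")
  fit <- suppressWarnings(stats::cor.test(u, v, method = "spearman",
                                          exact = FALSE))
  new_test_result(unname(fit$estimate), NA_real_, fit$p.value, "spearman")
}

# Surv object for one endpoint of a patient table
endpoint_surv <- function(records, endpoint) {
  endpoint <- match.arg(endpoint, c("os", "dfs", "mfs", "rfs"))
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(records)))
    stop2("records lack columns ", tcol, "/", ecol)
  survival::Surv(records[[tcol]], records[[ecol]])
}

#' Kaplan-Meier curves and log-rank test between TSR groups
#'
#' @param records Patient data.frame (see [simulate_cohort()] for the
#'   column dictionary).
#' @param group_field Grouping column name, e.g. `"group_itf"`.
#' @param endpoint One of `"os"`, `"dfs"`, `"mfs"`, `"rfs"`.
#' @return List with `test` (a `tsr_test`, method `logrank`) and `fit`
#'   (a [survival::survfit] object with per-arm product-limit curves).
#' @export
km_logrank <- function(records, group_field, endpoint = "os") {
  g <- factor(records[[group_field]])
  if (nlevels(droplevels(g)) < 2L)
    stop2("only one group level present in '", group_field, "'")
  s <- endpoint_surv(records, endpoint)
  sd <- survival::survdiff(s ~ g)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(s ~ g)
  list(test = new_test_result(sd$chisq, df, p, "logrank"), fit = fit)
}

new_regression_fit <- function(df, model, endpoint = NA_character_) {
  structure(list(table = df, model = model, endpoint = endpoint),
            class = "tsr_fit")
}

#' @export
print.tsr_fit <- function(x, ...) {
  cat(sprintf("<tsr_fit> %s%s\n", x$model,
              if (!is.na(x$endpoint)) paste0(" (", x$endpoint, ")") else ""))
  print(x$table, digits = 4)
  invisible(x)
}

# guard against separation / non-convergence: infinite or absurd effects
check_fit_sane <- function(coefs, ses, what) {
  if (any(!is.finite(coefs)) || any(!is.finite(ses)) ||
      any(abs(coefs) > 15) || any(ses > 1e3))
    stop2(what, ": non-convergence or complete separation ",
          "(|log effect| or SE diverged)")
}

fit_table <- function(coefs, ses, label = "hazard_ratio") {
  z <- coefs / ses
  data.frame(term = names(coefs),
             effect = exp(coefs),
             ci_lower = exp(coefs - 1.959964 * ses),
             ci_upper = exp(coefs + 1.959964 * ses),
             p_value = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

#' Cox proportional-hazards fit
#'
#' Categorical covariates are coded against their first factor level
#' (the published reference levels: male, <60, stage I, well, no, 1-3,
#' <5mm, no PNI, tumor_high).  Effects are hazard ratios with Wald 95%
#' confidence intervals.  Pass one covariate for a univariate fit or
#' several for an adjusted model.
#'
#' @param records Patient data.frame.
#' @param covariates Character vector of covariate column names.
#' @param endpoint One of `"os"`, `"dfs"`, `"mfs"`, `"rfs"`.
#' @return A `tsr_fit` with a per-term table of `effect` (HR),
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
cox_fit <- function(records, covariates, endpoint = "os") {
  if (length(covariates) < 1L) stop2("no covariates given")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stop2("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  s <- endpoint_surv(records, endpoint)
  if (sum(records[[paste0(endpoint, "_event")]]) < 1L)
    stop2("no events for endpoint '", endpoint, "'")
  fml <- stats::as.formula(paste("s ~", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records)
  coefs <- stats::coef(fit)
  ses <- sqrt(diag(stats::vcov(fit)))
  check_fit_sane(coefs, ses, "cox_fit")
  new_regression_fit(fit_table(coefs, ses), "cox", endpoint)
}

#' Logistic regression for perineural invasion
#'
#' Models PNI (yes vs no) from histological predictors; odds ratios with
#' Wald 95% confidence intervals.  `mode = "univariate"` fits one model
#' per predictor and stacks the rows; `mode = "multivariate"` adjusts
#' for all predictors jointly.
#'
#' @param records Patient data.frame with a `pni` factor (levels no/yes).
#' @param predictors Predictor column names; defaults to the five
#'   histological factors examined for PNI prediction.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return A `tsr_fit` with per-term odds ratios.
#' @export
logistic_pni <- function(records,
                         predictors = c("poi", "wpoi", "doi",
                                        "group_inner", "group_itf"),
                         mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  missing_cov <- setdiff(c("pni", predictors), names(records))
  if (length(missing_cov))
    stop2("missing column(s): ", paste(missing_cov, collapse = ", "))
  y <- records$pni
  if (length(unique(stats::na.omit(y))) < 2L)
    stop2("PNI outcome is constant: logistic model undefined")
  one_fit <- function(preds) {
    fml <- stats::as.formula(paste("pni ~", paste(preds, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, data = records,
                                       family = stats::binomial()))
    coefs <- stats::coef(fit)[-1]
    ses <- sqrt(diag(stats::vcov(fit)))[-1]
    check_fit_sane(coefs, ses, "logistic_pni")
    fit_table(coefs, ses)
  }
  tab <- if (mode == "multivariate") one_fit(predictors)
         else do.call(rbind, lapply(predictors, one_fit))
  new_regression_fit(tab, "logistic", "pni")
}

#' Percentage summary rounded to two decimals
#'
#' @param numerator,denominator Nonnegative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator` rounded to 2 decimal places.
#' @export
proportion_summary <- function(numerator, denominator) {
  if (!is_scalar_number(numerator) || !is_scalar_number(denominator))
    stop2("numerator and denominator must be numbers")
  if (denominator <= 0) stop2("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop2("need 0 <= numerator <= denominator")
  round(100 * numerator / denominator, 2)
}

#' Reproduce the baseline association tests from the printed tables
#'
#' Runs [chi_square_test()] over every [table1_fixtures()] table.
#'
#' @return data.frame with one row per table: `key`, `method`,
#'   `statistic`, `df`, `p_value`.
#' @export
baseline_association_tests <- function() {
  fx <- table1_fixtures()
  res <- lapply(names(fx), function(k) {
    t <- chi_square_test(fx[[k]])
    data.frame(key = k, method = t$method, statistic = t$statistic,
               df = t$df, p_value = t$p_value)
  })
  do.call(rbind, res)
}
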