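test_that("chi-square test agrees with the reference implementation", {
  set.seed(12)
  for (i in 1:20) {
    dims <- if (i <= 10) c(2, 2) else c(sample(2:4, 1), 2)
    counts <- matrix(rpois(prod(dims), 20) + 1, dims[1], dims[2])
    got <- chi_square_test(counts)
    want <- suppressWarnings(stats::chisq.test(counts))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square guards margins and honours the correction flag", {
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  t22 <- matrix(c(51, 34, 18, 11), 2)
  expect_identical(chi_square_test(t22)$method, "chi_square_yates")
  expect_identical(chi_square_test(t22, correct = FALSE)$method,
                   "chi_square")
  # Yates truncation makes p = 1 attainable exactly
  expect_equal(chi_square_test(t22)$p_value, 1)
  t42 <- table1_fixtures()$stage_inner
  expect_identical(chi_square_test(t42)$method, "chi_square")
  expect_equal(chi_square_test(t42)$df, 3L)
})

test_that("paired t-test detects the inner-vs-ITF shift", {
  # antisymmetry
  set.seed(5)
  x <- rnorm(50, 60, 10); y <- rnorm(50, 50, 10)
  a <- paired_t_test(x, y); b <- paired_t_test(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_gt(a$mean_difference, 0)
  expect_error(paired_t_test(x, x), "zero variance")

  # inner - ITF shift +15, sd 10, n = 114: p < 1e-4 in >= 99/100 seeds
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    inner <- rnorm(114, 65, 7)
    itf <- inner - rnorm(114, 15, 10)
    if (paired_t_test(inner, itf)$p_value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("spearman correlation handles monotone and degenerate input", {
  expect_equal(spearman_association(1:10, exp(1:10))$statistic, 1)
  expect_equal(spearman_association(1:10, -(1:10)^3)$statistic, -1)
  expect_error(spearman_association(rep(1, 5), 1:5), "constant")
})

test_that("log-rank test separates simulated arms and handles edge cases", {
  co <- simulate_cohort(cohort_config(n = 2000,
                                      hr_map = c(group_itf_low = 4.34),
                                      group_prevalence = 0.45,
                                      censor_rate = 0.3, seed = 77))
  res <- km_logrank(co, "group_itf", "dfs")
  expect_lt(res$test$p_value, 1e-4)
  expect_s3_class(res$fit, "survfit")

  # identical arms duplicated: p = 1
  half <- co[1:50, ]
  dup <- rbind(half, half)
  dup$group_itf <- factor(rep(c("tumor_high", "tumor_low"), each = 50),
                          levels = c("tumor_high", "tumor_low"))
  expect_equal(km_logrank(dup, "group_itf", "dfs")$test$p_value, 1)

  one_arm <- co[co$group_itf == "tumor_low", ]
  expect_error(km_logrank(one_arm, "group_itf", "dfs"), "one group")

  # an all-censored arm keeps its curve at 1
  cens <- dup
  cens$dfs_event[cens$group_itf == "tumor_low"] <- 0L
  fit <- km_logrank(cens, "group_itf", "dfs")$fit
  sm <- summary(fit)
  expect_true(all(sm$surv[sm$strata == "g=tumor_low"] == 1))
})

test_that("cox fit recovers parameters and reference relabelling inverts HRs", {
  co <- simulate_cohort(cohort_config(n = 2000,
                                      hr_map = c(group_itf_low = 4.34),
                                      group_prevalence = 0.45,
                                      censor_rate = 0.3,
                                      event_type_probs = c(death = 1,
                                                           relapse = 0,
                                                           metastasis = 0),
                                      seed = 3))
  fit <- cox_fit(co, "group_itf", "os")
  expect_gt(fit$table$effect, 3.7)
  expect_lt(fit$table$effect, 5.1)
  expect_true(fit$table$ci_lower <= 4.34 && 4.34 <= fit$table$ci_upper)

  # relabelling the reference level inverts the hazard ratio
  flipped <- co
  flipped$group_itf <- stats::relevel(flipped$group_itf, "tumor_low")
  fit2 <- cox_fit(flipped, "group_itf", "os")
  expect_equal(fit2$table$effect, 1 / fit$table$effect, tolerance = 1e-9)

  # multivariate adjustment set runs and returns one row per term
  mfit <- cox_fit(co, c("poi", "doi", "pni", "group_itf"), "os")
  expect_equal(nrow(mfit$table), 4L)
  expect_true(all(mfit$table$ci_lower <= mfit$table$effect &
                    mfit$table$effect <= mfit$table$ci_upper))
  expect_error(cox_fit(co, "not_a_column", "os"), "unknown")
})

test_that("cox null coverage is near nominal", {
  hits <- 0L
  for (s in 1:100) {
    co <- simulate_cohort(cohort_config(n = 250,
                                        hr_map = c(group_itf_low = 1),
                                        censor_rate = 0.3, seed = 1000 + s))
    tab <- cox_fit(co, "group_itf", "dfs")$table
    if (tab$ci_lower <= 1 && 1 <= tab$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits, 88L)
  expect_lte(hits, 100L)
})

test_that("univariate logistic OR equals the cross-product of printed counts", {
  # rebuild patient-level data from the printed PNI x inner-group table
  cts <- table1_fixtures()$pni_inner$counts
  rows <- list()
  for (p in 1:2) for (g in 1:2)
    rows[[length(rows) + 1L]] <- data.frame(
      pni = rownames(cts)[p], group_inner = colnames(cts)[g],
      count = cts[p, g])
  long <- do.call(rbind, rows)
  patients <- long[rep(seq_len(nrow(long)), long$count), 1:2]
  patients$pni <- factor(patients$pni, levels = c("no", "yes"))
  patients$group_inner <- factor(patients$group_inner,
                                 levels = c("tumor_high", "tumor_low"))
  fit <- logistic_pni(patients, predictors = "group_inner",
                      mode = "univariate")
  expect_equal(fit$table$effect, (17 * 68) / (12 * 17), tolerance = 1e-6)

  patients$pni <- factor("no", levels = c("no", "yes"))
  expect_error(logistic_pni(patients, predictors = "group_inner"),
               "constant")
})

test_that("multivariate logistic runs on simulated cohorts with null coverage", {
  hits <- 0L
  for (s in 1:60) {
    co <- simulate_cohort(cohort_config(n = 300, seed = 2000 + s))
    tab <- logistic_pni(co, predictors = "group_inner",
                        mode = "univariate")$table
    if (tab$ci_lower <= 1 && 1 <= tab$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits, 50L)

  co <- simulate_cohort(cohort_config(n = 400, seed = 44))
  mv <- logistic_pni(co, mode = "multivariate")
  expect_equal(nrow(mv$table), 5L)
})

test_that("proportion summaries round to two decimals", {
  expect_identical(proportion_summary(29, 114), 25.44)
  expect_identical(proportion_summary(38, 114), 33.33)
  expect_identical(proportion_summary(0, 50), 0)
  expect_error(proportion_summary(5, 0), "positive")
  expect_error(proportion_summary(6, 5), "<=")
})
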