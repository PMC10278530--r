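test_that("phantom band fractions hit their targets and truth is exact", {
  ph <- small_phantom(inner = 0.9, front = 0.3)
  tr <- ph$truth
  expect_gte(tr$true_inner_fraction, 0.85)
  expect_lte(tr$true_inner_fraction, 0.95)
  expect_gte(tr$true_front_fraction, 0.25)
  expect_lte(tr$true_front_fraction, 0.35)

  # truth fractions equal mask-pixel counts over band-pixel counts exactly
  for (z in c("inner", "itf")) {
    band <- tr$bands[[z]]$values
    got <- sum(tr$tumor_mask$values[band == 1L]) / sum(band)
    want <- if (z == "inner") tr$true_inner_fraction else
      tr$true_front_fraction
    expect_identical(got, want)
  }
})

test_that("zero-target phantom has an empty mask; config is validated", {
  ph <- small_phantom(inner = 0, front = 0)
  expect_identical(sum(ph$truth$tumor_mask$values), 0L)
  expect_identical(ph$truth$true_inner_fraction, 0)

  expect_error(phantom_config(image_size_px = c(60, 100), mpp = 16),
               "too small")
  expect_error(phantom_config(inner_target_fraction = 1.2), "<=")
  expect_error(phantom_config(mpp = 0), "mpp")
})

test_that("phantom generation is deterministic and seed-sensitive", {
  a <- generate_phantom(phantom_config(image_size_px = c(160, 100),
                                       mpp = 16, seed = 12))
  b <- generate_phantom(phantom_config(image_size_px = c(160, 100),
                                       mpp = 16, seed = 12))
  c <- generate_phantom(phantom_config(image_size_px = c(160, 100),
                                       mpp = 16, seed = 13))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$tumor_mask$values, b$truth$tumor_mask$values)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("cohort simulator recovers generative hazard ratios", {
  cfg <- cohort_config(n = 1500, hr_map = c(group_itf_low = 4.34),
                       censor_rate = 0.3, group_prevalence = 0.45,
                       event_type_probs = c(death = 1, relapse = 0,
                                            metastasis = 0),
                       seed = 202)
  co <- simulate_cohort(cfg)
  expect_identical(nrow(co), 1500L)
  # censoring close to its nominal rate
  expect_lt(abs(mean(co$os_event == 0) - 0.3), 0.05)
  fit <- cox_fit(co, "group_itf", "os")
  expect_gt(fit$table$effect, 3.7)
  expect_lt(fit$table$effect, 5.1)

  # null model: all-1 hazard ratios give near-zero coefficients
  co0 <- simulate_cohort(cohort_config(n = 5000,
                                       hr_map = c(group_itf_low = 1),
                                       seed = 7))
  fit0 <- cox_fit(co0, "group_itf", "dfs")
  expect_lt(abs(log(fit0$table$effect)), 0.1)
})

test_that("cohort endpoints follow the event-type conventions", {
  co <- simulate_cohort(cohort_config(n = 400, seed = 9))
  # every event endpoint shares the follow-up time
  expect_identical(co$os_time, co$dfs_time)
  # DFS counts every observed first event, so dominates the others
  expect_true(all(co$os_event <= co$dfs_event))
  expect_true(all(co$mfs_event <= co$dfs_event))
  expect_true(all(co$rfs_event <= co$dfs_event))
  # groups are consistent with the 50% TSR rule
  expect_identical(co$group_inner == "tumor_high", co$tsr_inner >= 50)
  expect_identical(co$group_itf == "tumor_high", co$tsr_itf >= 50)
  # determinism
  expect_identical(co, simulate_cohort(cohort_config(n = 400, seed = 9)))
})

test_that("degenerate cohort configurations error", {
  expect_error(cohort_config(n = 1), "'n'")
  expect_error(cohort_config(censor_rate = 1), "censor_rate")
  expect_error(cohort_config(hr_map = c(group_itf_low = -2)), "> 0")
  expect_error(cohort_config(hr_map = c(not_a_covariate = 2)), "unknown")
})

test_that("printed baseline tables are faithful fixtures", {
  fx <- table1_fixtures()
  expect_length(fx, 18L)
  totals <- vapply(fx, function(t) sum(t$counts), numeric(1))
  expect_true(all(totals == 114))
  # group marginals: 85/29 inner, 63/51 ITF
  for (k in names(fx)) {
    cs <- colSums(fx[[k]]$counts)
    if (grepl("_inner$", k)) expect_equal(unname(cs), c(85, 29))
    else expect_equal(unname(cs), c(63, 51))
  }
  expect_equal(unname(fx$pni_inner$counts),
               matrix(c(68, 17, 12, 17), 2))
  expect_equal(unname(fx$poi_itf$counts),
               matrix(c(44, 19, 20, 31), 2))
})
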