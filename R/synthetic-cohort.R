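## Proportional-hazards cohort simulator: a generative twin of the
## clinical cohort, with covariate prevalences matching the study
## population and exponential event times under user-specified hazard
## ratios.

# covariate prevalences of the 114-patient cohort (Table-1 marginals)
COHORT_PREVALENCE <- list(
  sex_female = 45 / 114, age_over60 = 70 / 114,
  stage = c(I = 8, II = 24, III = 20, IV = 62) / 114,
  differentiation_modpoor = 29 / 114, smoking_yes = 46 / 114,
  poi_high = 50 / 114, wpoi_high = 84 / 114, doi_high = 80 / 114,
  pni_yes = 34 / 114, group_inner_low = 29 / 114,
  group_itf_low = 51 / 114)

# relative frequency of first-event types (deaths 38, relapses 15,
# metastases 25 among the cohort's observed events)
DEFAULT_EVENT_TYPE_PROBS <- c(death = 38, relapse = 15, metastasis = 25) /
  (38 + 15 + 25)

#' Cohort simulator configuration
#'
#' @param n Number of patients (>= 2).
#' @param hr_map Named numeric vector of true hazard ratios (> 0).  Names
#'   refer to binary covariate indicators: `group_inner_low`,
#'   `group_itf_low`, `pni_yes`, `poi_high`, `wpoi_high`, `doi_high`,
#'   `smoking_yes`, `sex_female`, `age_over60`,
#'   `differentiation_modpoor`.  Default: the ITF tumor-low overall
#'   survival hazard ratio 4.34.
#' @param baseline_hazard Baseline event rate per month (> 0).  The
#'   default 0.015 gives a ~46-month median time to event at baseline,
#'   commensurate with the cohort's 52-month mean follow-up.
#' @param censor_rate Probability of independent censoring, in \[0, 1).
#' @param group_prevalence Probability a patient is ITF tumor-low.
#' @param event_type_probs Named probabilities for labelling each event
#'   death / relapse / metastasis.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 114, hr_map = c(group_itf_low = 4.34),
                          baseline_hazard = 0.015, censor_rate = 0.3,
                          group_prevalence = 51 / 114,
                          event_type_probs = DEFAULT_EVENT_TYPE_PROBS,
                          seed = 1L) {
  assert_scalar_number(n, "n", lower = 2)
  if (length(hr_map) > 0) {
    if (is.null(names(hr_map)) || any(names(hr_map) == ""))
      stop2("'hr_map' must be a named vector")
    unknown <- setdiff(names(hr_map),
                       setdiff(names(COHORT_PREVALENCE), "stage"))
    if (length(unknown))
      stop2("unknown hr_map covariate(s): ", paste(unknown, collapse = ", "))
    if (any(hr_map <= 0)) stop2("all hazard ratios must be > 0")
  }
  assert_scalar_number(baseline_hazard, "baseline_hazard", 0,
                       strict_lower = TRUE)
  if (!is_scalar_number(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stop2("'censor_rate' must lie in [0, 1): no events are observable at 1")
  if (!is_scalar_number(group_prevalence) || group_prevalence <= 0 ||
      group_prevalence >= 1)
    stop2("'group_prevalence' must lie strictly inside (0, 1)")
  if (length(event_type_probs) != 3L ||
      !setequal(names(event_type_probs), c("death", "relapse", "metastasis")))
    stop2("'event_type_probs' needs death/relapse/metastasis entries")
  structure(list(n = as.integer(n), hr_map = hr_map,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 group_prevalence = group_prevalence,
                 event_type_probs = event_type_probs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a survival cohort under exponential proportional hazards
#'
#' Covariates are drawn independently with the study population's
#' marginal prevalences (the ITF group uses `group_prevalence`).  Each
#' patient has one latent first event with per-patient hazard
#' `baseline_hazard * exp(sum(x * log(HR)))`, labelled death, relapse or
#' metastasis; censoring is independent with probability `censor_rate`.
#' Endpoints: OS counts only deaths; DFS counts any first event; RFS
#' treats metastasis as censoring; MFS treats relapse as censoring.  All
#' four share the follow-up time `min(T, C)` in months.
#'
#' @param config A [cohort_config()].
#' @return data.frame with one row per patient: `id`, clinical factors
#'   (`sex`, `age_group`, `stage`, `differentiation`, `smoking`, `poi`,
#'   `wpoi`, `doi`, `pni`), `tsr_inner`, `tsr_itf`, `group_inner`,
#'   `group_itf`, and `os/dfs/mfs/rfs` `_time` (months) and `_event`
#'   (0/1) columns.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop2("'config' must be a cohort_config")
  with_seed(config$seed, {
    n <- config$n
    pv <- COHORT_PREVALENCE
    rb <- function(p) stats::rbinom(n, 1L, p)
    ind <- list(
      sex_female = rb(pv$sex_female),
      age_over60 = rb(pv$age_over60),
      differentiation_modpoor = rb(pv$differentiation_modpoor),
      smoking_yes = rb(pv$smoking_yes),
      poi_high = rb(pv$poi_high),
      wpoi_high = rb(pv$wpoi_high),
      doi_high = rb(pv$doi_high),
      pni_yes = rb(pv$pni_yes),
      group_inner_low = rb(pv$group_inner_low),
      group_itf_low = rb(config$group_prevalence))
    stage <- sample(names(pv$stage), n, replace = TRUE, prob = pv$stage)

    loghaz <- rep(log(config$baseline_hazard), n)
    for (nm in names(config$hr_map))
      loghaz <- loghaz + ind[[nm]] * log(config$hr_map[[nm]])
    lambda <- exp(loghaz)
    t_event <- stats::rexp(n, rate = lambda)
    type <- sample(names(config$event_type_probs), n, replace = TRUE,
                   prob = config$event_type_probs)
    # exponential censoring with per-patient rate chosen so that
    # P(censored) = censor_rate exactly for every patient
    c_time <- if (config$censor_rate > 0)
      stats::rexp(n, rate = lambda * config$censor_rate /
                    (1 - config$censor_rate))
    else rep(Inf, n)

    observed <- t_event <= c_time
    fu <- pmin(t_event, c_time)
    ev <- function(types) as.integer(observed & type %in% types)

    lvl2 <- function(x, levels) factor(levels[x + 1L], levels = levels)
    tsr_draw <- function(low) ifelse(low == 1L, stats::runif(n, 5, 50),
                                     stats::runif(n, 50, 95))
    grp <- function(low) lvl2(low, c("tumor_high", "tumor_low"))

    data.frame(
      id = seq_len(n),
      sex = lvl2(ind$sex_female, c("male", "female")),
      age_group = lvl2(ind$age_over60, c("<60", ">=60")),
      stage = factor(stage, levels = names(pv$stage)),
      differentiation = lvl2(ind$differentiation_modpoor,
                             c("well", "moderate-poor")),
      smoking = lvl2(ind$smoking_yes, c("no", "yes")),
      poi = lvl2(ind$poi_high, c("1-3", "4-5")),
      wpoi = lvl2(ind$wpoi_high, c("1-3", "4-5")),
      doi = lvl2(ind$doi_high, c("<5mm", ">=5mm")),
      pni = lvl2(ind$pni_yes, c("no", "yes")),
      tsr_inner = tsr_draw(ind$group_inner_low),
      tsr_itf = tsr_draw(ind$group_itf_low),
      group_inner = grp(ind$group_inner_low),
      group_itf = grp(ind$group_itf_low),
      os_time = fu, os_event = ev("death"),
      dfs_time = fu, dfs_event = ev(c("death", "relapse", "metastasis")),
      mfs_time = fu, mfs_event = ev(c("death", "metastasis")),
      rfs_time = fu, rfs_event = ev(c("death", "relapse")))
  })
}

#' Write / read a simulated cohort as CSV
#'
#' Column dictionary: `id` integer; `sex` male/female; `age_group`
#' `<60`/`>=60`; `stage` I-IV; `differentiation` well/moderate-poor;
#' `smoking`, `pni` no/yes; `poi`, `wpoi` `1-3`/`4-5`; `doi`
#' `<5mm`/`>=5mm`; `tsr_inner`, `tsr_itf` percent; `group_inner`,
#' `group_itf` tumor_high/tumor_low; `*_time` months; `*_event` 0/1.
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fct <- list(sex = c("male", "female"), age_group = c("<60", ">=60"),
              stage = c("I", "II", "III", "IV"),
              differentiation = c("well", "moderate-poor"),
              smoking = c("no", "yes"), poi = c("1-3", "4-5"),
              wpoi = c("1-3", "4-5"), doi = c("<5mm", ">=5mm"),
              pni = c("no", "yes"),
              group_inner = c("tumor_high", "tumor_low"),
              group_itf = c("tumor_high", "tumor_low"))
  for (nm in names(fct))
    if (nm %in% names(df)) df[[nm]] <- factor(df[[nm]], levels = fct[[nm]])
  df
}
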