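test_that("covariate adjustment reduces to the crude fit when covariates are flat", {
  cfg <- clean_config(2500, seed = 37,
                      events = list(
                        death = list(intercept = -5.6, coef = c(),
                                     treatment_logor = -0.2),
                        mi = list(intercept = -5.6, coef = c(),
                                  treatment_logor = -0.2),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)
  co <- build_cohort(b)
  set(co, j = "age", value = 60)
  set(co, j = "risk", value = 0L)
  crude <- trial_effect(co, b, "itt", weighting = "none")
  adj <- covariate_adjusted_analysis(co, b)
  expect_equal(adj$rd, crude$rd, tolerance = 1e-6)
  expect_equal(adj$rr, crude$rr, tolerance = 1e-5)
})

test_that("prior-BB variants collapse onto the main analysis without prior users", {
  cfg <- clean_config(2500, seed = 41,
                      events = list(
                        death = list(intercept = -5.8, coef = c(),
                                     treatment_logor = -0.2),
                        mi = list(intercept = -5.8, coef = c(),
                                  treatment_logor = -0.2),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)  # prior_bb_fraction = 0
  co <- build_cohort(b)
  main <- trial_effect(co, b, "itt")
  pv <- prior_bb_variants(b)
  # identical cohorts; the extra indicator is constant so the weight
  # model is unchanged up to aliasing
  expect_equal(pv$prior_bb_included$rd, main$rd, tolerance = 1e-8)
  expect_equal(pv$prior_bb_admission_only$rd, main$rd, tolerance = 1e-8)
})

test_that("prior users with elevated hazards raise risks in variant 2a", {
  cfg <- clean_config(
    8000, seed = 43, prior_bb_fraction = 0.3, admission_agreement = 1,
    events = list(
      death = list(intercept = -6.2, coef = c(prior_bb = 1.2),
                   treatment_logor = 0),
      mi = list(intercept = -6.2, coef = c(prior_bb = 1.2),
                treatment_logor = 0),
      window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)
  co <- build_cohort(b)
  main <- trial_effect(co, b, "itt")
  pv <- prior_bb_variants(b)
  expect_gt(pv$prior_bb_included$risks[["beta_blocker"]],
            main$risks[["beta_blocker"]])
  expect_gt(pv$prior_bb_included$risks[["no_beta_blocker"]],
            main$risks[["no_beta_blocker"]])
  # 2a includes everyone, so its cohort is the largest
  expect_gt(nrow(build_cohort(b, eligibility_config(exclude_prior_bb = FALSE))),
            nrow(co))
})

test_that("missing-data variants agree under MCAR and zero missingness", {
  cfg <- clean_config(2500, seed = 47,
                      events = list(
                        death = list(intercept = -5.8, coef = c(),
                                     treatment_logor = -0.2),
                        mi = list(intercept = -5.8, coef = c(),
                                  treatment_logor = -0.2),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)  # no missingness configured
  co_med <- build_cohort(b, imputation = "median")
  co_cc <- build_cohort(b, imputation = "complete_case")
  # nothing missing: complete-case and median cohorts are the same data
  expect_equal(nrow(co_med), nrow(co_cc))
  main <- trial_effect(co_med, b, "itt")
  mv <- missingness_variants(b)
  expect_equal(mv$complete_case$rd, main$rd, tolerance = 1e-10)
  # categorizing continuous covariates only perturbs the weight model
  expect_lt(abs(mv$missing_category$rd - main$rd), 0.01)
})

test_that("the 90-day gap variant is a strict tightening of 180 days", {
  s <- make_subjects(1L, "beta_blocker", assignment_day = 1L)
  # one 120-day refill gap: censored under 90-day rule, not under 180
  disp <- rbind(disp_row(1L, "metoprolol", DAY0 + 1L, 100L, 100),
                disp_row(1L, "metoprolol", DAY0 + 220L, 600L, 100))
  b <- make_bundle(n = 1L, dispensations = disp)
  c180 <- nonadherence_date(s, b, adherence_config(gap_days = 180))
  c90 <- nonadherence_date(s, b, adherence_config(gap_days = 90))
  expect_equal(c90$censor_date, DAY0 + 100L + 90L)
  expect_gt(as.numeric(c180$censor_date), as.numeric(c90$censor_date))

  cfg <- generator_config(n_persons = 1500, seed = 53)
  bb <- generate_registry(cfg)
  co <- build_cohort(bb)
  a180 <- adherence_proportions(co, bb, adherence_config(gap_days = 180))
  a90 <- adherence_proportions(co, bb, adherence_config(gap_days = 90))
  expect_lte(a90[["beta_blocker"]], a180[["beta_blocker"]])
})

test_that("clone-censor bookkeeping and degenerate grace period", {
  cfg <- clean_config(1500, seed = 59,
                      events = list(
                        death = list(intercept = -5.8, coef = c(),
                                     treatment_logor = -0.2),
                        mi = list(intercept = -5.8, coef = c(),
                                  treatment_logor = -0.2),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)
  eff <- clone_censor_analysis(b, time = "saturated", weighting = "none")
  ck <- attr(eff, "clones")
  expect_equal(ck$n_clones, 2L * ck$n_persons)
  # with immediate initiation and no crossover, exactly one clone per
  # person is censored
  expect_equal(ck$bb_censored_at_grace + ck$nb_censored, ck$n_persons)
  expect_error(clone_censor_analysis(b, grace_days = 0), "grace")
})

test_that("sensitivity grid is complete and labelled", {
  cfg <- generator_config(n_persons = 2500, seed = 61)
  b <- generate_registry(cfg)
  grid <- sensitivity_grid(b)
  expect_setequal(grid$table$variant,
                  c("main_itt", "main_pp", "covariate_adjusted",
                    "prior_bb_included", "prior_bb_admission_only",
                    "complete_case", "missing_category", "clone_censor",
                    "pp_gap90"))
  expect_false(anyDuplicated(grid$table$variant) > 0)
  expect_true(all(nchar(grid$table$config_delta) > 0))
  expect_true(all(grid$table$risk_beta_blocker >= 0 &
                    grid$table$risk_beta_blocker <= 1))
})
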