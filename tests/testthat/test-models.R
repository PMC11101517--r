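saturated_model <- function(hazard, horizon = 60L) {
  hz <- CJ(arm = c("beta_blocker", "no_beta_blocker"),
           t = seq_len(horizon))
  hz[, `:=`(at_risk = 100, events = 100 * hazard, hazard = hazard)]
  structure(list(type = "saturated", hazards = hz, max_t = horizon,
                 zero_event_arms = character()),
            class = "pooled_logistic")
}

test_that("risk recursion matches the closed form for constant hazards", {
  rc <- risk_curves(saturated_model(0.01), horizon = 60)
  expect_equal(rc[arm == "beta_blocker" & t == 60, risk], 1 - 0.99^60,
               tolerance = 1e-12)
  expect_true(all(rc[, diff(risk) >= 0, by = arm]$V1))
  rc0 <- risk_curves(saturated_model(0), horizon = 60)
  expect_true(all(rc0$risk == 0))
  expect_error(risk_curves(saturated_model(0.01), horizon = 61),
               "extrapolation")
})

test_that("saturated pooled logistic reproduces the Kaplan-Meier estimator", {
  skip_if_not_installed("survival")
  cfg <- clean_config(150, seed = 23,
                      events = list(
                        death = list(intercept = -4.5, coef = c(),
                                     treatment_logor = -0.3),
                        mi = list(intercept = -4.5, coef = c(),
                                  treatment_logor = -0.3),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)
  co <- build_cohort(b)
  f <- expand_person_time(co, b)
  fit <- fit_pooled_logistic(f, time = "saturated")
  rc <- risk_curves(fit, horizon = max(f$t))
  ft <- f[, .(time = max(t), status = max(event)), by = .(person_id, arm)]
  for (a in unique(ft$arm)) {
    km <- survival::survfit(survival::Surv(time, status) ~ 1, data = ft[arm == a])
    km_risk <- 1 - summary(km, times = seq_len(max(f$t)), extend = TRUE)$surv
    expect_lt(max(abs(rc[arm == a, risk] - km_risk)), 1e-10)
  }
})

test_that("pooled logistic symmetry and weight-scale invariance", {
  # two arms with identical event patterns -> arm coefficient ~ 0
  f1 <- expand_person_time(
    make_subjects(1:60, rep("beta_blocker", 60)),
    make_bundle(n = 60, outcomes = oc_row(seq(2, 60, 4), "mi",
                                          DAY0 + 30L + seq(40, 1600, 110))))
  f2 <- copy(f1)[, `:=`(arm = "no_beta_blocker", person_id = person_id + 100L)]
  f <- rbind(f1, f2)
  fit <- fit_pooled_logistic(f, spline = spline_spec(c(3, 12, 30)))
  expect_lt(abs(coef(fit$fit)[["arm01"]]), 1e-6)

  w1 <- fit_pooled_logistic(f, weights = rep(1, nrow(f)),
                            spline = spline_spec(c(3, 12, 30)))
  w2 <- fit_pooled_logistic(f, weights = rep(2, nrow(f)),
                            spline = spline_spec(c(3, 12, 30)))
  expect_equal(coef(w1$fit), coef(w2$fit), tolerance = 1e-8)
})

test_that("risk contrasts and effect estimates do the arithmetic", {
  expect_equal(unname(risk_contrast(0.102, 0.119)["rd"]), -0.017,
               tolerance = 1e-12)
  expect_equal(round(risk_contrast(0.102, 0.119)[["rr"]], 2), 0.86)

  curves <- data.table(arm = rep(c("beta_blocker", "no_beta_blocker"),
                                 each = 60),
                       t = rep(1:60, 2),
                       hazard = 0.001,
                       risk = rep(seq(0.001, 0.06, length.out = 60), 2))
  eff <- effect_estimates(curves)
  expect_equal(eff$rd, 0)
  expect_equal(eff$rr, 1)
})

test_that("bootstrap is deterministic, percentile-based, and guarded", {
  s <- data.table(person_id = 1:50, x = rnorm(50))
  stat <- function(subjects, freq) c(m = weighted.mean(subjects$x, freq))
  b1 <- bootstrap_cis(stat, s, n_boot = 50, seed = 7)
  b2 <- bootstrap_cis(stat, s, n_boot = 50, seed = 7)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  b3 <- bootstrap_cis(stat, s, n_boot = 50, seed = 8)
  expect_false(identical(b1$lower, b3$lower))
  expect_true(b1$lower[["m"]] <= b1$estimate[["m"]])
  expect_true(b1$upper[["m"]] >= b1$estimate[["m"]])

  const <- function(subjects, freq) c(k = 1)
  bc <- bootstrap_cis(const, s, n_boot = 20, seed = 1)
  expect_equal(unname(bc$upper - bc$lower), 0)

  expect_error(bootstrap_cis(stat, s, n_boot = 1), "n_boot")
  # replicates fail (the full-sample pass succeeds) -> > 5% guard trips
  flaky <- function(subjects, freq) {
    if (any(freq != 1L)) stop("boom") else c(k = 1)
  }
  expect_error(bootstrap_cis(flaky, s, n_boot = 10, seed = 1), "failed")
})

test_that("standardized risks reduce to unadjusted when covariates are flat", {
  cfg <- clean_config(2000, seed = 29,
                      events = list(
                        death = list(intercept = -5.5, coef = c(),
                                     treatment_logor = -0.2),
                        mi = list(intercept = -5.5, coef = c(),
                                  treatment_logor = -0.2),
                        window_death_prob = 0, window_mi_prob = 0))
  b <- generate_registry(cfg)
  co <- build_cohort(b)
  set(co, j = "age", value = 60)
  set(co, j = "risk", value = 1L)
  f <- expand_person_time(co, b)
  plain <- fit_pooled_logistic(f)
  adj <- fit_pooled_logistic(f, extra_covariates = c("age", "risk"),
                             subjects = co)
  r1 <- risk_curves(plain, 60)
  r2 <- risk_curves(adj, 60)
  expect_equal(r1$risk, r2$risk, tolerance = 1e-8)
})
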