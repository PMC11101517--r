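test_that("generation handles the empty case and is deterministic", {
  b0 <- generate_registry(clean_config(0))
  expect_equal(nrow(b0$persons), 0L)
  expect_equal(nrow(b0$dispensations), 0L)
  expect_equal(nrow(b0$outcomes), 0L)

  cfg <- generator_config(n_persons = 400, seed = 9)
  b1 <- generate_registry(cfg)
  b2 <- generate_registry(cfg)
  for (tb in c("persons", "dispensations", "diagnoses", "outcomes"))
    expect_identical(b1[[tb]], b2[[tb]])
  b3 <- generate_registry(generator_config(n_persons = 400, seed = 10))
  expect_false(identical(b1$outcomes, b3$outcomes))
})

test_that("generated bundles satisfy the registry invariants", {
  cfg <- generator_config(n_persons = 2000, seed = 3)
  b <- generate_registry(cfg)
  expect_false(anyDuplicated(b$persons$person_id) > 0)
  expect_true(all(b$persons$angio_date >= b$persons$index_date))
  deaths <- b$outcomes[event == "death", .N, by = person_id]
  expect_true(all(deaths$N == 1L))
  lo <- cfg$recruitment_window[1] - 1096L
  for (tb in c("dispensations", "diagnoses", "outcomes")) {
    dates <- b[[tb]][[grep("date", names(b[[tb]]), value = TRUE)[1]]]
    expect_true(all(dates >= lo & dates <= cfg$study_end))
  }
  # 3-year lookback fully populated: prior-BB users have dispensations
  # strictly inside their own lookback window
  prior <- merge(b$dispensations[drug_class %in% c("metoprolol",
                                                   "bisoprolol")],
                 b$persons[, .(person_id, angio_date)], by = "person_id")
  prior <- prior[dispense_date <= angio_date]
  expect_gt(nrow(prior), 0)
  expect_true(all(prior$dispense_date >= prior$angio_date - 1096L))
})

test_that("an assignment coefficient induces confounded prescribing", {
  cfg <- clean_config(10000, seed = 5,
                      assignment = list(intercept = 0, coef = c(risk = 2)))
  b <- generate_registry(cfg)
  win <- merge(
    b$dispensations[drug_class %in% c("metoprolol", "bisoprolol")],
    b$persons[, .(person_id, angio_date, risk)], by = "person_id")
  win <- win[dispense_date > angio_date &
               dispense_date <= angio_date + 30L]
  prescribed <- b$persons$person_id %in% win$person_id
  p1 <- mean(prescribed[b$persons$risk == 1])
  p0 <- mean(prescribed[b$persons$risk == 0])
  expect_gt(p1 - p0, 0.10)
  # monotone confounding: a larger coefficient widens the crude gap
  cfg2 <- clean_config(10000, seed = 5,
                       assignment = list(intercept = 0, coef = c(risk = 3)))
  b2 <- generate_registry(cfg2)
  win2 <- merge(
    b2$dispensations[drug_class %in% c("metoprolol", "bisoprolol")],
    b2$persons[, .(person_id, angio_date, risk)], by = "person_id")
  win2 <- win2[dispense_date > angio_date &
                 dispense_date <= angio_date + 30L]
  prescribed2 <- b2$persons$person_id %in% win2$person_id
  gap2 <- mean(prescribed2[b2$persons$risk == 1]) -
    mean(prescribed2[b2$persons$risk == 0])
  expect_gt(gap2, p1 - p0)
})

test_that("missingness injection hits configured rates and nothing else", {
  cfg <- clean_config(400, seed = 2)
  b <- generate_registry(cfg)
  b_same <- inject_missingness(b, cfg)  # all rates absent -> unchanged
  expect_identical(b$persons, b_same$persons)

  cfg1 <- clean_config(400, seed = 2, missingness = c(age = 1))
  b1 <- generate_registry(cfg1)
  expect_true(all(is.na(b1$persons$age)))
  expect_identical(b1$persons$risk, b$persons$risk)

  cfg2 <- clean_config(10000, seed = 6, missingness = c(age = 0.155))
  b2 <- generate_registry(cfg2)
  frac <- mean(is.na(b2$persons$age))
  expect_lt(abs(frac - 0.155), 3 * sqrt(0.155 * 0.845 / 10000))
})

test_that("oracle: null effect, closed form, and recursion agreement", {
  # null treatment effect -> true RD ~ 0
  orc0 <- compute_true_effects(clean_config(1000), n_oracle = 20000,
                               seed = 4)
  for (oc in orc0$effects$outcome) {
    row <- orc0$effects[outcome == oc]
    se <- sqrt(row$mc_se_treated^2 + row$mc_se_control^2)
    expect_lt(abs(row$true_rd_5y), 3 * max(se, 1e-12))
  }
  # constant MI hazard 0.01, no deaths -> risk = 1 - 0.99^60
  cfg <- clean_config(1000,
                      events = list(
                        death = list(intercept = -Inf, coef = c(),
                                     treatment_logor = 0),
                        mi = list(intercept = qlogis(0.01), coef = c(),
                                  treatment_logor = 0),
                        window_death_prob = 0, window_mi_prob = 0))
  orc <- compute_true_effects(cfg, n_oracle = 50000, seed = 8)
  target <- 1 - 0.99^60
  row <- orc$effects[outcome == "mi"]
  expect_lt(abs(row$risk_treated - target), 3 * row$mc_se_treated)
  expect_lt(abs(row$risk_control - target), 3 * row$mc_se_control)

  # independent interval recursion with competing constant hazards
  hd <- 0.004; hm <- 0.007
  cfg2 <- clean_config(1000,
                       events = list(
                         death = list(intercept = qlogis(hd), coef = c(),
                                      treatment_logor = 0),
                         mi = list(intercept = qlogis(hm), coef = c(),
                                   treatment_logor = 0),
                         window_death_prob = 0, window_mi_prob = 0))
  orc2 <- compute_true_effects(cfg2, n_oracle = 50000, seed = 12)
  # recursion oracle: risk(t) = risk(t-1) + h(t) * survival(t-1)
  surv <- cumprod(rep((1 - hd) * (1 - hm), 60))
  comp_rec <- 1 - surv
  death_rec <- 1 - cumprod(rep(1 - hd, 60))
  # MI counted at t needs mi at t (geometric hm) and death not before t
  mi_rec <- cumsum(hm * c(1, head(surv, -1)))
  got <- orc2$risks[arm == "beta_blocker"]
  for (oc in c("composite", "death", "mi")) {
    ref <- switch(oc, composite = comp_rec, death = death_rec, mi = mi_rec)
    g <- got[outcome == oc][order(t)]
    expect_lt(max(abs(g$risk - ref)), 4 * max(g$mc_se) + 1e-9)
  }
  # oracle invariants: monotone, bounded, composite dominates components
  wide <- dcast(orc2$risks[arm == "beta_blocker"], t ~ outcome,
                value.var = "risk")
  expect_true(all(wide$composite >= wide$death - 1e-12))
  expect_true(all(wide$composite >= wide$mi - 1e-12))
  expect_true(all(diff(wide$composite) >= -1e-12))
  expect_true(all(wide$composite >= 0 & wide$composite <= 1))
})
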