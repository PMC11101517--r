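test_that("dispensation coverage follows the pill-count arithmetic", {
  d1 <- disp_row(1L, "metoprolol", DAY0, 100L, 50)
  seg <- dispensation_coverage(d1)
  expect_equal(as.integer(seg$end_date - seg$start_date) + 1L, 50L)

  d2 <- disp_row(1L, "bisoprolol", DAY0, 30L, 5)
  seg2 <- dispensation_coverage(d2)
  expect_equal(as.integer(seg2$end_date - seg2$start_date) + 1L, 30L)

  # stockpiling: two 50-day dispensations on days 0 and 20 merge to 0-99
  d3 <- rbind(disp_row(1L, "metoprolol", DAY0, 100L, 50),
              disp_row(1L, "metoprolol", DAY0 + 20L, 100L, 50))
  seg3 <- dispensation_coverage(d3)
  expect_equal(nrow(seg3), 1L)
  expect_equal(seg3$start_date, DAY0)
  expect_equal(seg3$end_date, DAY0 + 99L)
  # without stockpiling the refill restarts from its dispense date
  seg3b <- dispensation_coverage(d3, adherence_config(stockpiling = FALSE))
  expect_equal(seg3b$end_date, DAY0 + 20L + 49L)

  expect_error(dispensation_coverage(disp_row(1L, "statin", DAY0, 30L, 20)),
               "daily dose")
})

test_that("beta-blocker arm censoring follows the 180-day gap rule", {
  s <- make_subjects(1L, "beta_blocker", assignment_day = 1L)
  # coverage days 1-200 (rel. angio), next dispensation at day 370:
  # gap 170 < 180 -> continuous through both segments, then exhaustion
  disp <- rbind(disp_row(1L, "metoprolol", DAY0 + 1L, 200L, 100),
                disp_row(1L, "metoprolol", DAY0 + 370L, 200L, 100))
  b <- make_bundle(persons = NULL, n = 1L, dispensations = disp)
  cens <- nonadherence_date(s, b)
  expect_equal(cens$censor_date, DAY0 + 370L + 199L + 180L)

  # exhaustion: coverage ends, no refill -> censor at end + 180
  b2 <- make_bundle(n = 1L, dispensations =
                      disp_row(1L, "metoprolol", DAY0 + 1L, 200L, 100))
  cens2 <- nonadherence_date(s, b2)
  expect_equal(cens2$censor_date, DAY0 + 200L + 180L)

  # a >= 180-day gap censors even though a later refill exists
  b3 <- make_bundle(n = 1L, dispensations = rbind(
    disp_row(1L, "metoprolol", DAY0 + 1L, 200L, 100),
    disp_row(1L, "metoprolol", DAY0 + 450L, 200L, 100)))
  cens3 <- nonadherence_date(s, b3)
  expect_equal(cens3$censor_date, DAY0 + 200L + 180L)

  # contraindication on/before coverage end excuses the gap
  b4 <- make_bundle(n = 1L, dispensations =
                      disp_row(1L, "metoprolol", DAY0 + 1L, 200L, 100),
                    diagnoses = dx_row(1L, "copd", DAY0 + 150L))
  cens4 <- nonadherence_date(s, b4)
  expect_true(is.na(cens4$censor_date))

  # shrinking the gap (180 -> 90) never delays a censor date
  for (bb in list(b2, b3)) {
    c180 <- nonadherence_date(s, bb, adherence_config(gap_days = 180))
    c90 <- nonadherence_date(s, bb, adherence_config(gap_days = 90))
    expect_true(c90$censor_date <= c180$censor_date)
  }
})

test_that("no-beta-blocker arm censoring respects new indications", {
  s <- make_subjects(1L, "no_beta_blocker")
  t0 <- DAY0 + 30L
  b <- make_bundle(n = 1L, dispensations =
                     disp_row(1L, "metoprolol", t0 + 370L, 100L, 50))
  cens <- nonadherence_date(s, b)
  expect_equal(cens$censor_date, t0 + 370L)

  # heart-failure diagnosis before the dispensation suppresses censoring
  b2 <- make_bundle(n = 1L, dispensations =
                      disp_row(1L, "metoprolol", t0 + 370L, 100L, 50),
                    diagnoses = dx_row(1L, "heart_failure_dx", t0 + 350L))
  cens2 <- nonadherence_date(s, b2)
  expect_true(is.na(cens2$censor_date))

  # never dispensing is full adherence
  b3 <- make_bundle(n = 1L)
  expect_true(is.na(nonadherence_date(s, b3)$censor_date))
})

test_that("person-time expansion maps days to intervals correctly", {
  s <- make_subjects(1L, "beta_blocker")
  t0 <- DAY0 + 30L
  # composite event on day 70 -> intervals 1..3, event closes interval 3
  b <- make_bundle(n = 1L, outcomes = oc_row(1L, "mi", t0 + 70L))
  f <- expand_person_time(s, b, outcome_kind = "composite")
  expect_equal(f$t, 1:3)
  expect_equal(f$event_composite, c(0L, 0L, 1L))
  expect_equal(f$event, f$event_composite)

  # death on day 100 with MI outcome under the total effect: the person
  # remains, contributing event-free intervals to the horizon
  b2 <- make_bundle(n = 1L, outcomes = oc_row(1L, "death", t0 + 100L))
  f2 <- expand_person_time(s, b2, outcome_kind = "mi", total_effect = TRUE)
  expect_equal(nrow(f2), 60L)
  expect_true(all(f2$event == 0L))
  expect_equal(sum(f2$event_death), 1L)
  # without the total-effect convention death censors at its interval
  f2b <- expand_person_time(s, b2, outcome_kind = "mi",
                            total_effect = FALSE)
  expect_equal(nrow(f2b), 3L)

  # per-protocol censoring on day 380 -> 12 complete intervals, the last
  # flagged as artificially censored
  b3 <- make_bundle(n = 1L)
  cens <- data.table(person_id = 1L, censor_date = t0 + 380L)
  f3 <- expand_person_time(s, b3, censor_dates = cens,
                           outcome_kind = "composite")
  expect_equal(nrow(f3), 12L)
  expect_equal(f3$artificially_censored, c(rep(0L, 11L), 1L))
  expect_true(all(f3$event == 0L))
  cf <- attr(f3, "censor_frame")
  expect_equal(cf[cens == 1L, t], 13L)

  # event before time zero is an upstream alignment error
  b4 <- make_bundle(n = 1L, outcomes = oc_row(1L, "mi", t0 - 5L))
  expect_error(expand_person_time(s, b4), "alignment")
})

test_that("expansion invariants: interval count, ITT invariance, coverage", {
  cfg <- generator_config(n_persons = 800, seed = 31)
  b <- generate_registry(cfg)
  co <- build_cohort(b)
  itt <- expand_person_time(co, b)
  nint <- itt[, .(n = max(t), first = min(t)), by = person_id]
  expect_true(all(nint$first == 1L))
  expect_true(all(nint$n <= 60L))
  # contiguity
  expect_equal(nrow(itt), sum(nint$n))

  # ITT expansion is invariant to dispensation history after time zero
  b2 <- b
  t0 <- setNames(as.integer(co$time_zero), co$person_id)
  keep <- !(b2$dispensations$person_id %in% co$person_id &
              as.integer(b2$dispensations$dispense_date) >
                t0[as.character(b2$dispensations$person_id)] + 10)
  b2$dispensations <- b2$dispensations[keep]
  itt2 <- expand_person_time(co, b2)
  cols <- c("person_id", "arm", "t", "event", "event_death", "event_mi",
            "event_composite")
  expect_identical(itt[, cols, with = FALSE], itt2[, cols, with = FALSE])

  # coverage conservation: covered days never exceed dispensed days
  bb <- b$dispensations[drug_class %in% c("metoprolol", "bisoprolol")]
  segs <- dispensation_coverage(bb)
  covered <- segs[, sum(as.numeric(end_date - start_date) + 1)]
  dispensed <- bb[, sum(floor(pill_count * pill_dose_mg /
                                ifelse(drug_class == "metoprolol", 100, 5)))]
  expect_lte(covered, dispensed)
})
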