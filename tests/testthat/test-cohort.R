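test_that("each eligibility criterion excludes exactly its violator", {
  n <- 20L
  persons <- data.table(
    person_id = 1:n, index_date = DAY0 - 2L, angio_date = DAY0,
    admission_record_prior_bb = 0L, discharge_bb = 0L,
    age = 60, heart_rate = 70)
  persons[person_id == 2L, angio_date := as.Date(NA)]        # no angiography
  persons[person_id == 3L, angio_date := index_date + 40L]   # angio too late
  persons[person_id == 7L, admission_record_prior_bb := 1L]  # admission flag
  persons[person_id == 8L, heart_rate := 130]                # vital threshold
  dx <- rbind(
    dx_row(4L, "stroke", DAY0 - 730L),                # contraindication, 2 y
    dx_row(5L, "stroke", DAY0 - 1461L),               # 4 y: outside lookback
    dx_row(9L, "chronic_heart_failure", DAY0 - 100L), # indication
    dx_row(10L, "dementia", DAY0 - 50L))              # compliance exclusion
  disp <- rbind(
    disp_row(6L, "metoprolol", DAY0 - 365L, 100L, 50),  # prior BB use
    disp_row(12L, "statin", DAY0 + 40L, 100L, 20))      # statin too late
  oc <- rbind(oc_row(13L, "death", DAY0 + 10L),
              oc_row(14L, "mi", DAY0 + 29L))
  b <- make_bundle(persons = persons, dispensations = disp, diagnoses = dx,
                   outcomes = oc)
  # persons 11 and 12 must fail the statin criterion: remove 11's records
  b$dispensations <- b$dispensations[
    !(person_id == 11L & drug_class %in% c("statin", "antithrombotic")) &
      !(person_id == 12L & drug_class %in% c("statin", "antithrombotic") &
          dispense_date == DAY0 + 1L)]

  el <- apply_eligibility(b)
  fl <- el$flowchart
  expect_equal(fl$n_remaining,
               c(20L, 18L, 17L, 13L, 12L, 10L, 8L))
  expect_setequal(el$eligible, c(1L, 5L, 15:20))
  # flowchart monotone; exclusions + final cohort partition the input
  expect_true(all(diff(fl$n_remaining) <= 0))

  masks <- attr(el, "masks")
  expect_true(masks[person_id == 5L, no_contraindication])
  expect_false(masks[person_id == 4L, no_contraindication])
})

test_that("final eligible set is invariant to criterion order", {
  cfg <- generator_config(n_persons = 600, seed = 21)
  b <- generate_registry(cfg)
  e1 <- apply_eligibility(b)
  e2 <- apply_eligibility(b, criterion_order = c(
    "statin_antithrombotic", "no_compliance_exclusion",
    "no_bb_indication", "no_contraindication"))
  expect_setequal(e1$eligible, e2$eligible)
  expect_false(identical(e1$flowchart$n_remaining,
                         e2$flowchart$n_remaining))
})

test_that("arm assignment follows the prescription-window rule", {
  persons <- data.table(
    person_id = 1:4, index_date = DAY0 - 2L, angio_date = DAY0,
    admission_record_prior_bb = 0L, discharge_bb = c(0L, 0L, 0L, 1L),
    age = 60, heart_rate = 70)
  disp <- rbind(
    disp_row(1L, "metoprolol", DAY0 + 10L, 100L, 50),
    disp_row(3L, "metoprolol", DAY0 + 31L, 100L, 50))
  b <- make_bundle(persons = persons, dispensations = disp)
  s <- assign_arm(b, 1:4)
  setkey(s, person_id)
  expect_equal(s[.(1L), arm], "beta_blocker")
  expect_equal(s[.(1L), assignment_date], DAY0 + 10L)
  expect_equal(s[.(1L), time_zero], DAY0 + 30L)
  expect_equal(s[.(2L), arm], "no_beta_blocker")
  expect_true(is.na(s[.(2L), assignment_date]))
  expect_equal(s[.(2L), time_zero], DAY0 + 30L)
  # day-31 dispensation: no beta blockers at baseline
  expect_equal(s[.(3L), arm], "no_beta_blocker")
  # discharge-record fallback: assigned at discharge date
  expect_equal(s[.(4L), arm], "beta_blocker")
  expect_equal(s[.(4L), assignment_date], DAY0 + 3L)
  # everyone gets exactly one arm
  expect_true(all(s$arm %in% c("beta_blocker", "no_beta_blocker")))

  # a beta-blocker dispensation before angiography for an "eligible"
  # person is an upstream inconsistency
  b2 <- make_bundle(persons = persons[1:2],
                    dispensations = disp_row(2L, "metoprolol", DAY0 - 5L,
                                             100L, 50))
  expect_error(assign_arm(b2, 1:2), "inconsistency")
})

test_that("baseline imputation strategies behave as defined", {
  s <- make_subjects(1:4, rep("beta_blocker", 4))
  s$age <- c(1, 2, NA, 100)
  set(s, j = "miss_age", value = as.integer(is.na(s$age)))
  m <- impute_baseline(s, "median")
  expect_equal(m$age, c(1, 2, 2, 100))  # median of {1, 2, 100}

  cc <- impute_baseline(s, "complete_case")
  expect_equal(cc$person_id, c(1L, 2L, 4L))

  s2 <- make_subjects(1:1000, rep("beta_blocker", 1000))
  set.seed(1)
  s2$age <- rnorm(1000)
  s2$age[sample(1000, 155)] <- NA
  mc <- impute_baseline(s2, "missing_category")
  expect_true(is.character(mc$age))
  expect_equal(sort(unique(mc$age)),
               sort(c(paste0("q", 1:5), "missing")))
  expect_equal(mean(mc$age == "missing"), 0.155)
  expect_equal(attr(mc, "covinfo")$kinds[["age"]], "categorical")

  s3 <- make_subjects(1:2, rep("beta_blocker", 2))
  s3$age <- c(NA_real_, NA_real_)
  expect_error(impute_baseline(s3, "median"), "age")
})
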