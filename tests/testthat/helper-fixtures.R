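library(data.table)

DAY0 <- as.Date("2012-01-10")  # default angiography date for fixtures

# minimal covariate bookkeeping matching ttemu's internal covinfo layout
fixture_covinfo <- function() {
  list(names = c("age", "heart_rate"),
       kinds = c(age = "continuous", heart_rate = "continuous"),
       means = c(age = 60, heart_rate = 70),
       sds = c(age = 10, heart_rate = 12),
       levels = list(age = NULL, heart_rate = NULL))
}

# hand-built registry bundle; persons defaults to clean, eligible people
make_bundle <- function(n = 1L, persons = NULL, dispensations = NULL,
                        diagnoses = NULL, outcomes = NULL,
                        angio = DAY0, study_end = as.Date("2017-12-31"),
                        auto_statin = TRUE) {
  if (is.null(persons)) {
    persons <- data.table(
      person_id = seq_len(n),
      index_date = angio - 2L,
      angio_date = angio,
      admission_record_prior_bb = 0L,
      discharge_bb = 0L,
      age = 60, heart_rate = 70)
  }
  empty_disp <- data.table(person_id = integer(), drug_class = character(),
                           dispense_date = as.Date(character()),
                           pill_count = integer(), pill_dose_mg = numeric())
  empty_dx <- data.table(person_id = integer(), condition_code = character(),
                         date = as.Date(character()), source = character())
  empty_oc <- data.table(person_id = integer(), event = character(),
                         date = as.Date(character()))
  dispensations <- rbind(empty_disp, dispensations, fill = TRUE)
  if (auto_statin) {
    sa <- data.table(
      person_id = rep(persons$person_id, 2L),
      drug_class = rep(c("statin", "antithrombotic"),
                       each = nrow(persons)),
      dispense_date = rep(persons$angio_date, 2L) + 1L,
      pill_count = 100L, pill_dose_mg = 20)
    dispensations <- rbind(dispensations, sa, fill = TRUE)
  }
  b <- list(persons = persons,
            dispensations = dispensations,
            diagnoses = rbind(empty_dx, diagnoses, fill = TRUE),
            outcomes = rbind(empty_oc, outcomes, fill = TRUE),
            meta = list(config = list(study_end = study_end),
                        seed = 0L, covinfo = fixture_covinfo(),
                        config_hash = "fixture"))
  class(b) <- "registry_bundle"
  b
}

disp_row <- function(id, drug, date, pills, dose) {
  data.table(person_id = id, drug_class = drug, dispense_date = date,
             pill_count = as.integer(pills), pill_dose_mg = dose)
}

dx_row <- function(id, code, date, source = "inpatient") {
  data.table(person_id = id, condition_code = code, date = date,
             source = source)
}

oc_row <- function(id, event, date) {
  data.table(person_id = id, event = event, date = date)
}

# a hand-built eligible subject table (bypassing assign_arm)
make_subjects <- function(ids, arm, angio = DAY0, assignment_day = 10L) {
  s <- data.table(
    person_id = ids,
    arm = arm,
    angio_date = angio,
    assignment_date = fifelse(arm == "beta_blocker",
                              angio + assignment_day, as.Date(NA)),
    time_zero = angio + 30L,
    age = 60, heart_rate = 70)
  setattr(s, "covinfo", fixture_covinfo())
  s
}

# generator config with every optional complication switched off; pass
# overrides for the piece a test exercises
clean_config <- function(n, seed = 1L, ...) {
  args <- list(
    n_persons = n, seed = seed,
    covariates = list(
      list(name = "age", kind = "continuous", mean = 60, sd = 10),
      list(name = "risk", kind = "binary", prob = 0.5)),
    assignment = list(intercept = 0, coef = c()),
    events = list(
      death = list(intercept = -6.5, coef = c(), treatment_logor = 0),
      mi = list(intercept = -6.5, coef = c(), treatment_logor = 0),
      window_death_prob = 0, window_mi_prob = 0),
    adherence = list(
      discontinuation = list(intercept = -Inf, coef = c()),
      crossover = list(intercept = -Inf, coef = c()),
      refill_delay_range = c(-10, 20),
      discontinuation_contra_prob = 0,
      crossover_indication_prob = 0),
    contraindication_rate = 0, new_indication_rate = 0,
    renal_onset_rate = 0, prior_bb_fraction = 0,
    admission_agreement = 1, discharge_only_fraction = 0,
    statin_antithrombotic_fraction = 1,
    contraindication_history_rate = 0, indication_history_rate = 0,
    compliance_history_rate = 0, stale_history_rate = 0,
    comed_fractions = c(arb = 0, ace_inhibitor = 0, ccb = 0, diuretic = 0,
                        nitrate = 0, diabetes_tx = 0),
    missingness = c(),
    recruitment_window = as.Date(c("2010-09-01", "2011-09-01")),
    study_end = as.Date("2017-12-31"))
  do.call(generator_config, utils::modifyList(args, list(...)))
}
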