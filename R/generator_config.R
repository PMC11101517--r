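#' Default baseline covariate specification for the synthetic registry
#'
#' Twelve covariates typical of a post-MI registry: demographics, risk
#' factors, presentation and vital signs/labs.  Marginal distributions are
#' loosely calibrated to a Swedish post-MI population.  Continuous
#' covariates are standardized with their own `mean`/`sd` when they enter
#' any generator model, so model coefficients are per-SD log odds.
#'
#' @return list of covariate definitions (name, kind, parameters).
#' @export
default_covariates <- function() {
  list(
    list(name = "age",           kind = "continuous",  mean = 65,  sd = 11),
    list(name = "female",        kind = "binary",      prob = 0.21),
    list(name = "smoking",       kind = "categorical",
         levels = c("never", "ex", "current"), probs = c(0.42, 0.35, 0.23)),
    list(name = "hypertension",  kind = "binary",      prob = 0.31),
    list(name = "diabetes",      kind = "binary",      prob = 0.11),
    list(name = "prev_mi",       kind = "binary",      prob = 0.04),
    list(name = "heart_failure", kind = "binary",      prob = 0.03),
    list(name = "stemi",         kind = "binary",      prob = 0.43),
    list(name = "heart_rate",    kind = "continuous",  mean = 73,  sd = 14),
    list(name = "sbp",           kind = "continuous",  mean = 146, sd = 22),
    list(name = "ldl",           kind = "continuous",  mean = 3.3, sd = 1.0),
    list(name = "creatinine",    kind = "continuous",  mean = 82,  sd = 20)
  )
}

# Model-term names allowed beyond declared covariates: prior beta-blocker
# use (baseline) and renal disease onset (time-varying).
SPECIAL_MODEL_TERMS <- c("prior_bb", "renal")

BB_DRUGS <- c("metoprolol", "bisoprolol")
COMED_CLASSES <- c("arb", "ace_inhibitor", "ccb", "diuretic", "nitrate",
                   "diabetes_tx")

CONTRAINDICATION_CODES <- c("bradycardia", "av_block_2_3", "hypotension",
                            "syncope", "asthma", "copd", "stroke")
INDICATION_CODES <- c("chronic_heart_failure", "atrial_flicker_flutter")
COMPLIANCE_CODES <- c("psychiatric_disorder", "dementia")
NEW_INDICATION_CODES <- c("hypertension_dx", "angina", "arrhythmia",
                          "heart_failure_dx")

#' Synthetic-registry generator configuration
#'
#' Defines the data-generating process: confounded beta-blocker prescribing
#' within an assignment window after angiography, discrete-time death and
#' reinfarction hazards with a configurable treatment effect, refill-based
#' adherence with informative discontinuation and crossover,
#' contraindication/indication histories, co-medication, and missingness in
#' continuous labs.  All model coefficients are named log-odds terms on
#' declared covariates (continuous ones standardized), plus the special
#' terms `prior_bb` (baseline) and `renal` (time-varying).
#'
#' @param n_persons number of persons to generate.
#' @param recruitment_window pair of dates for the index hospitalization.
#' @param study_end administrative end of data (all records truncated here).
#' @param covariates covariate specification, see [default_covariates()].
#' @param assignment list(intercept, coef): log-odds model for receiving a
#'   beta-blocker prescription within the assignment window.
#' @param events list with `death` and `mi` sub-models
#'   (intercept = per-interval baseline log odds, coef, treatment_logor =
#'   true conditional log odds ratio), plus `window_death_prob` /
#'   `window_mi_prob`, the probability of an event inside the 30-day
#'   assignment window.
#' @param adherence list with `discontinuation` and `crossover` per-interval
#'   log-odds models, `refill_delay_range` (days, relative to coverage end),
#'   `discontinuation_contra_prob` (probability that a discontinuation is
#'   preceded by a contraindication diagnosis) and
#'   `crossover_indication_prob` (probability that a crossover dispensation
#'   is preceded by a new-indication diagnosis).
#' @param contraindication_rate,new_indication_rate per-interval background
#'   probabilities of a post-baseline contraindication / new-indication
#'   diagnosis.
#' @param renal_onset_rate per-interval probability of renal-disease onset.
#' @param prior_bb_fraction fraction with beta-blocker use in the 3-year
#'   lookback (emitted both as dispensations and as an admission flag).
#' @param admission_agreement probability that the admission-record flag
#'   agrees with the dispensation history.
#' @param discharge_only_fraction fraction of prescribed persons whose only
#'   window evidence is the discharge record (no window dispensation).
#' @param discharge_offset_days discharge date = angiography + offset.
#' @param statin_antithrombotic_fraction fraction on both statins and
#'   antithrombotics at baseline (default 0.94).
#' @param contraindication_history_rate,indication_history_rate,
#'   compliance_history_rate fractions with a lookback diagnosis of each
#'   kind (these drive eligibility exclusions).
#' @param stale_history_rate fraction with a contraindication diagnosis just
#'   *outside* the 3-year lookback (exercises the lookback boundary).
#' @param comed_fractions named per-class fractions of baseline users of
#'   other cardiovascular drugs (refilled during follow-up).
#' @param assignment_window_days days after angiography within which a
#'   dispensation counts as assignment (and time zero offset).
#' @param horizon_months follow-up horizon in 30.4375-day months.
#' @param missingness named per-covariate missing probabilities for
#'   continuous covariates.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_persons = 10000L,
    recruitment_window = as.Date(c("2010-09-01", "2017-09-10")),
    study_end = as.Date("2017-12-31"),
    covariates = default_covariates(),
    assignment = list(
      intercept = 2.2,
      coef = c(age = -0.35, heart_rate = 0.45, stemi = 0.40,
               prev_mi = -0.55, heart_failure = -0.50, sbp = 0.15)
    ),
    events = list(
      death = list(intercept = -6.95,
                   coef = c(age = 0.65, heart_failure = 0.55,
                            creatinine = 0.30, prev_mi = 0.30),
                   treatment_logor = -0.04),
      mi = list(intercept = -7.00,
                coef = c(prev_mi = 0.60, diabetes = 0.30, ldl = 0.20,
                         age = 0.25),
                treatment_logor = -0.27),
      window_death_prob = 0.004,
      window_mi_prob = 0.006
    ),
    adherence = list(
      discontinuation = list(intercept = -4.15, coef = c(age = 0.10)),
      crossover = list(intercept = -5.15, coef = c(heart_rate = 0.10)),
      refill_delay_range = c(-10, 40),
      discontinuation_contra_prob = 0.30,
      crossover_indication_prob = 0.50
    ),
    contraindication_rate = 0.0015,
    new_indication_rate = 0.0015,
    renal_onset_rate = 0.002,
    prior_bb_fraction = 0.20,
    admission_agreement = 0.90,
    discharge_only_fraction = 0.03,
    discharge_offset_days = 3L,
    statin_antithrombotic_fraction = 0.94,
    contraindication_history_rate = 0.08,
    indication_history_rate = 0.05,
    compliance_history_rate = 0.04,
    stale_history_rate = 0.05,
    comed_fractions = c(arb = 0.18, ace_inhibitor = 0.70, ccb = 0.17,
                        diuretic = 0.13, nitrate = 0.50, diabetes_tx = 0.11),
    assignment_window_days = 30L,
    horizon_months = 60L,
    missingness = c(ldl = 0.155, creatinine = 0.044),
    seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    recruitment_window = as.Date(recruitment_window),
    study_end = as.Date(study_end),
    covariates = covariates,
    assignment = assignment,
    events = events,
    adherence = adherence,
    contraindication_rate = contraindication_rate,
    new_indication_rate = new_indication_rate,
    renal_onset_rate = renal_onset_rate,
    prior_bb_fraction = prior_bb_fraction,
    admission_agreement = admission_agreement,
    discharge_only_fraction = discharge_only_fraction,
    discharge_offset_days = as.integer(discharge_offset_days),
    statin_antithrombotic_fraction = statin_antithrombotic_fraction,
    contraindication_history_rate = contraindication_history_rate,
    indication_history_rate = indication_history_rate,
    compliance_history_rate = compliance_history_rate,
    stale_history_rate = stale_history_rate,
    comed_fractions = comed_fractions,
    assignment_window_days = as.integer(assignment_window_days),
    horizon_months = as.integer(horizon_months),
    missingness = missingness,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_persons) || cfg$n_persons < 0L)
    stop("configuration error: 'n_persons' must be a non-negative integer",
         call. = FALSE)
  if (length(cfg$recruitment_window) != 2L ||
      any(is.na(cfg$recruitment_window)))
    stop("configuration error: 'recruitment_window' must be two dates",
         call. = FALSE)
  if (cfg$recruitment_window[2] < cfg$recruitment_window[1])
    stop("configuration error: 'recruitment_window' start exceeds end",
         call. = FALSE)
  if (cfg$study_end <= cfg$recruitment_window[2])
    stop("configuration error: 'study_end' must follow the recruitment window",
         call. = FALSE)
  for (f in c("contraindication_rate", "new_indication_rate",
              "renal_onset_rate", "prior_bb_fraction", "admission_agreement",
              "discharge_only_fraction", "statin_antithrombotic_fraction",
              "contraindication_history_rate", "indication_history_rate",
              "compliance_history_rate", "stale_history_rate"))
    assert_prob(cfg[[f]], f)
  assert_prob(cfg$events$window_death_prob, "events$window_death_prob")
  assert_prob(cfg$events$window_mi_prob, "events$window_mi_prob")
  assert_prob(cfg$comed_fractions, "comed_fractions")
  if (length(cfg$missingness))
    assert_prob(cfg$missingness, "missingness")
  assert_positive(cfg$assignment_window_days, "assignment_window_days")
  assert_positive(cfg$horizon_months, "horizon_months")
  cov_names <- vapply(cfg$covariates, `[[`, "", "name")
  if (anyDuplicated(cov_names))
    stop("configuration error: duplicated covariate names in 'covariates'",
         call. = FALSE)
  allowed <- c(cov_names, SPECIAL_MODEL_TERMS)
  check_coef <- function(model, what) {
    nms <- sub(":.*$", "", names(model$coef %||% numeric()))
    bad <- setdiff(nms, allowed)
    if (length(bad))
      stop("configuration error: '", what, "' references undeclared ",
           "covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_coef(cfg$assignment, "assignment")
  check_coef(cfg$events$death, "events$death")
  check_coef(cfg$events$mi, "events$mi")
  check_coef(cfg$adherence$discontinuation, "adherence$discontinuation")
  check_coef(cfg$adherence$crossover, "adherence$crossover")
  miss_bad <- setdiff(names(cfg$missingness), cov_names)
  if (length(miss_bad))
    stop("configuration error: 'missingness' references undeclared ",
         "covariates: ", paste(miss_bad, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# covariate bookkeeping: names, kinds, and standardization parameters
covariate_info <- function(covariates) {
  kinds <- vapply(covariates, `[[`, "", "kind")
  names(kinds) <- vapply(covariates, `[[`, "", "name")
  means <- vapply(covariates, function(cv)
    if (cv$kind == "continuous") cv$mean else NA_real_, 0)
  sds <- vapply(covariates, function(cv)
    if (cv$kind == "continuous") cv$sd else NA_real_, 0)
  names(means) <- names(sds) <- names(kinds)
  list(names = names(kinds), kinds = kinds, means = means, sds = sds,
       levels = setNames(lapply(covariates, function(cv) cv$levels %||% NULL),
                         names(kinds)))
}

# draw n rows of covariates per the spec
draw_covariates <- function(covariates, n) {
  out <- data.table(person_id = seq_len(n))
  for (cv in covariates) {
    set(out, j = cv$name, value = switch(
      cv$kind,
      continuous = rnorm(n, cv$mean, cv$sd),
      binary = as.integer(runif(n) < cv$prob),
      categorical = sample(cv$levels, n, replace = TRUE, prob = cv$probs),
      stop("configuration error: unknown covariate kind '", cv$kind, "'",
           call. = FALSE)
    ))
  }
  out
}

# linear predictor of a named-coefficient log-odds model; continuous
# covariates standardized by their spec mean/sd; categorical covariates get
# per-level coefficients named "cov:level" (reference = first level).
model_lp <- function(model, X, info, extras = list()) {
  lp <- rep(model$intercept %||% 0, nrow(X))
  cf <- model$coef %||% numeric()
  for (nm in names(cf)) {
    if (nm %in% names(extras)) {
      lp <- lp + cf[[nm]] * extras[[nm]]
    } else if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      lp <- lp + cf[[nm]] * as.numeric(X[[parts[1]]] == parts[2])
    } else if (identical(info$kinds[[nm]], "continuous")) {
      lp <- lp + cf[[nm]] * (X[[nm]] - info$means[[nm]]) / info$sds[[nm]]
    } else {
      lp <- lp + cf[[nm]] * as.numeric(X[[nm]])
    }
  }
  lp
}
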