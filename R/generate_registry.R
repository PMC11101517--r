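#' Generate a synthetic post-MI registry
#'
#' Simulates the four registry tables the emulation pipeline consumes:
#' `persons` (index hospitalization, angiography date, baseline covariates,
#' admission/discharge beta-blocker flags), `dispensations` (drug class,
#' date, pill count, pill dose), `diagnoses` (symbolic condition codes with
#' a source register) and `outcomes` (death, myocardial infarction).  The
#' data-generating process has the statistical structure the analysis
#' assumes: prescribing is confounded by baseline covariates,
#' non-adherence can be informative (driven by covariates and renal-disease
#' onset), and death and MI compete on a discrete 30.4375-day grid.
#'
#' Event histories are simulated on the analysis grid itself; a discrete
#' interval `t` is materialized as the calendar day at the interval
#' midpoint, so dates round-trip exactly through [interval_of()].
#'
#' @param config a [generator_config()].
#' @return object of class `registry_bundle`: list of the four tables plus
#'   `meta` (config, seed, covariate info).
#' @export
generate_registry <- function(config) {
  validate_generator_config(config)
  info <- covariate_info(config$covariates)
  if (config$n_persons == 0L) return(empty_bundle(config, info))

  withr::with_seed(config$seed, {
    bundle <- generate_registry_impl(config, info)
  })
  bundle
}

empty_tables <- function(info) {
  persons <- data.table(
    person_id = integer(), index_date = as.Date(character()),
    angio_date = as.Date(character()),
    admission_record_prior_bb = integer(), discharge_bb = integer()
  )
  for (nm in info$names)
    persons[[nm]] <- if (info$kinds[[nm]] == "categorical") character()
                     else numeric()
  list(
    persons = persons,
    dispensations = data.table(
      person_id = integer(), drug_class = character(),
      dispense_date = as.Date(character()), pill_count = integer(),
      pill_dose_mg = numeric()),
    diagnoses = data.table(
      person_id = integer(), condition_code = character(),
      date = as.Date(character()), source = character()),
    outcomes = data.table(
      person_id = integer(), event = character(),
      date = as.Date(character()))
  )
}

empty_bundle <- function(config, info) {
  b <- empty_tables(info)
  b$meta <- list(config = config, seed = config$seed, covinfo = info,
                 config_hash = config_hash(config))
  class(b) <- "registry_bundle"
  b
}

generate_registry_impl <- function(config, info) {
  n <- config$n_persons
  H <- config$horizon_months
  W <- config$assignment_window_days
  r0 <- as.integer(config$recruitment_window[1])
  r1 <- as.integer(config$recruitment_window[2])
  send <- as.integer(config$study_end)
  lookback <- 1096L

  X <- draw_covariates(config$covariates, n)

  index_day <- r0 + sample.int(r1 - r0 + 1L, n, replace = TRUE) - 1L
  angio_day <- index_day + sample(0:3, n, replace = TRUE)
  t0_day <- angio_day + W

  prior_bb <- as.integer(runif(n) < config$prior_bb_fraction)
  agree <- runif(n) < config$admission_agreement
  admission_flag <- ifelse(agree, prior_bb, 1L - prior_bb)

  ## --- treatment assignment (confounded prescribing) ---------------------
  p_rx <- plogis(model_lp(config$assignment, X, info,
                          extras = list(prior_bb = prior_bb, renal = 0)))
  prescribed <- runif(n) < p_rx
  discharge_only <- prescribed & runif(n) < config$discharge_only_fraction
  window_disp_day <- angio_day + sample.int(W, n, replace = TRUE)
  late_first_day <- angio_day + W + sample(5:30, n, replace = TRUE)
  first_bb_day <- fifelse(discharge_only, late_first_day, window_disp_day)

  ## --- window (days 1..W after angiography) events ------------------------
  win_death <- runif(n) < config$events$window_death_prob
  win_mi <- runif(n) < config$events$window_mi_prob
  win_death_day <- angio_day + sample.int(W, n, replace = TRUE)
  win_mi_day <- angio_day + sample.int(W, n, replace = TRUE)
  win_mi <- win_mi & (!win_death | win_mi_day <= win_death_day)

  ## --- renal-disease onset (time-varying prognostic factor) ---------------
  renal_int <- draw_geom_interval(n, config$renal_onset_rate)
  R <- outer(ifelse(is.na(renal_int), Inf, as.numeric(renal_int)),
             seq_len(H), `<=`) * 1  # n x H indicator

  ## --- adherence processes ------------------------------------------------
  disc_int <- draw_process_interval(config$adherence$discontinuation, X, info,
                                    prior_bb, R, H)
  cross_int <- draw_process_interval(config$adherence$crossover, X, info,
                                     prior_bb, R, H)

  ## --- post-baseline event processes (depend on current exposure) --------
  Tmat <- matrix(0, n, H)
  idx_rx <- which(prescribed)
  if (length(idx_rx))
    Tmat[idx_rx, ] <- outer(fifelse(is.na(disc_int[idx_rx]), Inf,
                                    as.numeric(disc_int[idx_rx])),
                            seq_len(H), `>`) * 1
  idx_cx <- which(!prescribed & !is.na(cross_int))
  if (length(idx_cx))
    Tmat[idx_cx, ] <- outer(as.numeric(cross_int[idx_cx]), seq_len(H),
                            `<=`) * 1

  death_int <- draw_event_interval(config$events$death, X, info, prior_bb,
                                   R, Tmat, H)
  mi_int <- draw_event_interval(config$events$mi, X, info, prior_bb,
                                R, Tmat, H)
  # window deaths preclude any post-baseline history
  death_int[win_death] <- NA_integer_
  mi_int[win_death] <- NA_integer_
  disc_int[win_death] <- NA_integer_
  cross_int[win_death] <- NA_integer_
  # a new MI cannot postdate death
  mi_int[!is.na(mi_int) & !is.na(death_int) & mi_int > death_int] <-
    NA_integer_
  idx_cx <- which(!prescribed & !is.na(cross_int))

  death_day <- t0_day + interval_mid_day(death_int)
  mi_day <- t0_day + interval_mid_day(mi_int)
  end_of_data <- pmin(send, t0_day + as.integer(ceiling(H * MONTH_DAYS)))
  alive_until <- fifelse(win_death, win_death_day,
                         fifelse(is.na(death_int), end_of_data, death_day))

  ## --- outcomes table ------------------------------------------------------
  outcomes <- rbind(
    data.table(person_id = which(win_death), event = "death",
               date = win_death_day[win_death]),
    data.table(person_id = which(win_mi), event = "mi",
               date = win_mi_day[win_mi]),
    data.table(person_id = which(!is.na(death_int)), event = "death",
               date = death_day[!is.na(death_int)]),
    data.table(person_id = which(!is.na(mi_int)), event = "mi",
               date = mi_day[!is.na(mi_int)])
  )
  outcomes <- outcomes[date <= send]

  ## --- dispensations -------------------------------------------------------
  disp <- list()
  # prior beta-blocker use in the 3-year lookback
  idx_pb <- which(prior_bb == 1L)
  if (length(idx_pb)) {
    k_pb <- sample(2:5, length(idx_pb), replace = TRUE)
    pid <- rep(idx_pb, k_pb)
    disp$prior <- data.table(
      person_id = pid,
      drug_class = "metoprolol",
      dispense_day = rep(angio_day[idx_pb], k_pb) -
        sample.int(lookback - 1L, length(pid), replace = TRUE),
      pill_count = 100L, pill_dose_mg = 50)
  }
  # statins and antithrombotics at baseline
  idx_sa <- which(runif(n) < config$statin_antithrombotic_fraction)
  if (length(idx_sa)) {
    disp$statin <- data.table(
      person_id = rep(idx_sa, 2L),
      drug_class = rep(c("statin", "antithrombotic"), each = length(idx_sa)),
      dispense_day = rep(angio_day[idx_sa], 2L) +
        sample(0:25, 2L * length(idx_sa), replace = TRUE),
      pill_count = 100L, pill_dose_mg = rep(c(20, 75), each = length(idx_sa)))
  }
  # beta-blocker refill sequences: initiators from first dispensation,
  # crossovers in the unprescribed from the crossover date
  cross_day <- t0_day + interval_mid_day(cross_int)
  starters <- data.table(
    person_id = c(which(prescribed), idx_cx),
    start_day = c(first_bb_day[prescribed], cross_day[idx_cx]),
    stop_day = c(
      pmin(alive_until, end_of_data,
           fifelse(is.na(disc_int), Inf,
                   as.numeric(t0_day + interval_mid_day(disc_int))))[prescribed],
      as.numeric(pmin(alive_until, end_of_data))[idx_cx])
  )
  starters <- starters[start_day <= stop_day & start_day <= send]
  if (nrow(starters)) {
    m <- nrow(starters)
    drug <- sample(BB_DRUGS, m, replace = TRUE, prob = c(0.8, 0.2))
    disp$bb <- generate_refills(starters$person_id, starters$start_day,
                                starters$stop_day, drug, send,
                                config$adherence$refill_delay_range)
  }
  # co-medication refills (time-varying dispensation covariates)
  comed <- list()
  for (cls in names(config$comed_fractions)) {
    idx <- which(runif(n) < config$comed_fractions[[cls]])
    if (!length(idx)) next
    fdays <- pmax(pmin(alive_until[idx], end_of_data[idx]) - angio_day[idx],
                  0)
    k <- as.integer(pmin(floor(fdays / 120) + 1L, 16L))
    pid <- rep(idx, k)
    ord <- sequence(k) - 1L
    comed[[cls]] <- data.table(
      person_id = pid,
      drug_class = cls,
      dispense_day = rep(angio_day[idx], k) + ord * 120L +
        sample(0:20, length(pid), replace = TRUE),
      pill_count = 90L, pill_dose_mg = 10)
  }
  dispensations <- rbindlist(c(disp, comed), use.names = TRUE)
  if (!nrow(dispensations))
    dispensations <- data.table(person_id = integer(),
                                drug_class = character(),
                                dispense_day = integer(),
                                pill_count = integer(),
                                pill_dose_mg = numeric())
  dispensations <- dispensations[dispense_day <= send &
                                   dispense_day >= r0 - lookback]

  ## --- diagnoses -----------------------------------------------------------
  dx <- list()
  draw_history <- function(rate, codes, src, lo = 30L, hi = 1095L,
                           require_late_entry = FALSE) {
    idx <- which(runif(n) < rate)
    if (require_late_entry) idx <- idx[angio_day[idx] - hi >= r0 - lookback]
    if (!length(idx)) return(NULL)
    data.table(
      person_id = idx,
      condition_code = sample(codes, length(idx), replace = TRUE),
      diag_day = angio_day[idx] -
        (lo + sample.int(hi - lo + 1L, length(idx), replace = TRUE) - 1L),
      source = sample(src, length(idx), replace = TRUE))
  }
  dx$contra_hist <- draw_history(config$contraindication_history_rate,
                                 CONTRAINDICATION_CODES,
                                 c("inpatient", "outpatient"))
  dx$stale <- draw_history(config$stale_history_rate,
                           CONTRAINDICATION_CODES,
                           c("inpatient", "outpatient"),
                           lo = 1097L, hi = 1400L,
                           require_late_entry = TRUE)
  dx$indic_hist <- draw_history(config$indication_history_rate,
                                INDICATION_CODES, "registry")
  dx$compl_hist <- draw_history(config$compliance_history_rate,
                                COMPLIANCE_CODES, "registry")
  # renal onset during follow-up
  idx_rn <- which(!is.na(renal_int) & renal_int <= H)
  if (length(idx_rn)) {
    d <- t0_day[idx_rn] + interval_mid_day(renal_int[idx_rn])
    keep <- d <= pmin(alive_until[idx_rn], send)
    if (any(keep))
      dx$renal <- data.table(person_id = idx_rn[keep],
                             condition_code = "renal_disease",
                             diag_day = d[keep], source = "inpatient")
  }
  # background post-baseline contraindications / new indications
  draw_background <- function(rate, codes) {
    bint <- draw_geom_interval(n, rate)
    idx <- which(!is.na(bint) & bint <= H)
    if (!length(idx)) return(NULL)
    d <- t0_day[idx] + interval_mid_day(bint[idx])
    keep <- d <= pmin(alive_until[idx], send)
    if (!any(keep)) return(NULL)
    data.table(person_id = idx[keep],
               condition_code = sample(codes, sum(keep), replace = TRUE),
               diag_day = d[keep],
               source = sample(c("inpatient", "outpatient"), sum(keep),
                               replace = TRUE))
  }
  dx$contra_post <- draw_background(config$contraindication_rate,
                                    CONTRAINDICATION_CODES)
  dx$indic_post <- draw_background(config$new_indication_rate,
                                   NEW_INDICATION_CODES)
  # contraindication preceding a discontinuation (adherence override)
  idx_dc <- which(prescribed & !is.na(disc_int) &
                    runif(n) < config$adherence$discontinuation_contra_prob)
  if (length(idx_dc)) {
    d <- t0_day[idx_dc] + interval_mid_day(disc_int[idx_dc]) -
      sample.int(10L, length(idx_dc), replace = TRUE)
    keep <- d <= pmin(alive_until[idx_dc], send)
    if (any(keep))
      dx$disc_contra <- data.table(
        person_id = idx_dc[keep],
        condition_code = sample(CONTRAINDICATION_CODES, sum(keep),
                                replace = TRUE),
        diag_day = d[keep], source = "inpatient")
  }
  # new indication preceding a crossover dispensation
  idx_ci <- idx_cx[runif(length(idx_cx)) <
                     config$adherence$crossover_indication_prob]
  if (length(idx_ci)) {
    d <- cross_day[idx_ci] - sample.int(14L, length(idx_ci), replace = TRUE)
    keep <- d <= send
    if (any(keep))
      dx$cross_ind <- data.table(
        person_id = idx_ci[keep],
        condition_code = sample(NEW_INDICATION_CODES, sum(keep),
                                replace = TRUE),
        diag_day = d[keep], source = "outpatient")
  }
  diagnoses <- rbindlist(dx, use.names = TRUE)
  if (!nrow(diagnoses))
    diagnoses <- data.table(person_id = integer(),
                            condition_code = character(),
                            diag_day = integer(), source = character())
  diagnoses <- diagnoses[diag_day >= r0 - lookback & diag_day <= send]

  ## --- assemble ------------------------------------------------------------
  persons <- data.table(
    person_id = seq_len(n),
    index_date = as.Date(index_day, origin = "1970-01-01"),
    angio_date = as.Date(angio_day, origin = "1970-01-01"),
    admission_record_prior_bb = admission_flag,
    discharge_bb = as.integer(discharge_only)
  )
  persons <- cbind(persons, X[, !"person_id"])

  dispensations[, dispense_date := as.Date(dispense_day,
                                           origin = "1970-01-01")]
  dispensations[, dispense_day := NULL]
  setcolorder(dispensations, c("person_id", "drug_class", "dispense_date",
                               "pill_count", "pill_dose_mg"))
  diagnoses[, date := as.Date(diag_day, origin = "1970-01-01")]
  diagnoses[, diag_day := NULL]
  setcolorder(diagnoses, c("person_id", "condition_code", "date", "source"))
  outcomes[, date := as.Date(date, origin = "1970-01-01")]

  setorder(dispensations, person_id, dispense_date, drug_class)
  setorder(diagnoses, person_id, date, condition_code)
  setorder(outcomes, person_id, date, event)

  bundle <- list(persons = persons, dispensations = dispensations,
                 diagnoses = diagnoses, outcomes = outcomes,
                 meta = list(config = config, seed = config$seed,
                             covinfo = info,
                             config_hash = config_hash(config)))
  class(bundle) <- "registry_bundle"
  inject_missingness(bundle, config)
}

# first interval (1-based) at which a constant per-interval probability
# fires; NA when it never does
draw_geom_interval <- function(n, rate) {
  if (rate <= 0) return(rep(NA_integer_, n))
  k <- rgeom(n, rate) + 1L
  k[k > 10000L] <- NA_integer_
  k
}

# first interval at which a covariate-dependent per-interval logistic
# process fires (possibly renal-dependent, hence time-varying)
draw_process_interval <- function(model, X, info, prior_bb, R, H) {
  n <- nrow(X)
  lp0 <- model_lp(strip_coef(model, "renal"), X, info,
                  extras = list(prior_bb = prior_bb))
  cr <- (model$coef %||% numeric())["renal"]
  cr <- if (is.na(cr)) 0 else cr
  Hz <- plogis(matrix(lp0, n, H) + cr * R)
  first_true_col(matrix(runif(n * H), n, H) < Hz)
}

draw_event_interval <- function(model, X, info, prior_bb, R, Tmat, H,
                                U = NULL) {
  n <- nrow(X)
  lp0 <- model_lp(strip_coef(model, "renal"), X, info,
                  extras = list(prior_bb = prior_bb))
  cr <- (model$coef %||% numeric())["renal"]
  cr <- if (is.na(cr)) 0 else cr
  Hz <- plogis(matrix(lp0, n, H) + cr * R +
                 (model$treatment_logor %||% 0) * Tmat)
  if (is.null(U)) U <- matrix(runif(n * H), n, H)
  first_true_col(U < Hz)
}

strip_coef <- function(model, drop) {
  model$coef <- model$coef[setdiff(names(model$coef %||% numeric()), drop)]
  model
}

#' @importFrom stats rgeom
# Vectorized refill engine: each dispensation's intended duration is
# pill_count * pill_dose / daily_dose days; the next refill is drawn at
# coverage end + delay (early refills allowed) while before stop_day.
generate_refills <- function(person_id, start_day, stop_day, drug,
                             study_end_day, delay_range,
                             daily_dose = c(metoprolol = 100, bisoprolol = 5)) {
  m <- length(person_id)
  rows <- vector("list", 64L)
  k <- 0L
  active <- seq_len(m)
  disp_day <- as.numeric(start_day)
  cov_end <- rep(-Inf, m)
  while (length(active) && k < 64L) {
    k <- k + 1L
    a <- active
    pills <- sample(c(90L, 100L), length(a), replace = TRUE)
    dose <- fifelse(drug[a] == "metoprolol",
                    sample(c(50, 100), length(a), replace = TRUE), 5)
    dur <- floor(pills * dose / daily_dose[drug[a]])
    rows[[k]] <- data.table(person_id = person_id[a],
                            drug_class = drug[a],
                            dispense_day = as.integer(disp_day[a]),
                            pill_count = pills, pill_dose_mg = dose)
    start <- pmax(disp_day[a], cov_end[a] + 1)
    cov_end[a] <- start + dur - 1
    delay <- sample(delay_range[1]:delay_range[2], length(a), replace = TRUE)
    disp_day[a] <- cov_end[a] + delay
    active <- a[disp_day[a] <= stop_day[a] & disp_day[a] <= study_end_day]
  }
  rbindlist(rows[seq_len(k)])
}
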