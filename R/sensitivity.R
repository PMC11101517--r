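# append a derived baseline covariate to a cohort (and its covinfo)
add_cohort_covariate <- function(subjects, name, values, kind = "binary") {
  set(subjects, j = name, value = values)
  info <- attr(subjects, "covinfo")
  if (!name %in% info$names) {
    info$names <- c(info$names, name)
    info$kinds[name] <- kind
    info$means[name] <- NA_real_
    info$sds[name] <- NA_real_
    info$levels[name] <- list(NULL)
  }
  setattr(subjects, "covinfo", info)
  subjects
}

#' Covariate-adjusted outcome model (sensitivity to modelling assumptions)
#'
#' Replaces IP weighting by entering the baseline covariates directly in
#' the pooled logistic outcome model; risks are standardized over the
#' empirical covariate distribution (parametric g-formula).
#'
#' @inheritParams trial_effect
#' @return `effect_estimates`.
#' @export
covariate_adjusted_analysis <- function(subjects, bundle,
                                        outcome_kind = "composite",
                                        spline = spline_spec(),
                                        horizon = 60L, n_boot = 0L,
                                        seed = 1L) {
  trial_effect(subjects, bundle, contrast = "itt",
               outcome_kind = outcome_kind,
               weighting = "covariate_adjusted", spline = spline,
               horizon = horizon, n_boot = n_boot, seed = seed)
}

#' Prior-beta-blocker eligibility variants
#'
#' Variant 2a drops the prior-use exclusion entirely and adds a prior-use
#' indicator (dispensation history or admission record) to the weight
#' model.  Variant 2b applies the exclusion using the admission record
#' only and adds the dispensation-history indicator to the weight model.
#'
#' @param bundle a `registry_bundle`.
#' @param eligibility base [eligibility_config()].
#' @param outcome_kind,spline,horizon,n_boot,seed,imputation analysis
#'   settings.
#' @return named list of `effect_estimates` (`prior_bb_included`,
#'   `prior_bb_admission_only`).
#' @export
prior_bb_variants <- function(bundle, eligibility = eligibility_config(),
                              outcome_kind = "composite",
                              spline = spline_spec(), horizon = 60L,
                              n_boot = 0L, seed = 1L,
                              imputation = "median") {
  el_2a <- eligibility
  el_2a$exclude_prior_bb <- FALSE
  co_2a <- build_cohort(bundle, el_2a, imputation)
  co_2a <- add_cohort_covariate(
    co_2a, "prior_bb_any",
    as.integer(co_2a$prior_bb_disp | co_2a$admission_record_prior_bb))
  eff_2a <- trial_effect(co_2a, bundle, "itt", outcome_kind,
                         spline = spline, horizon = horizon,
                         n_boot = n_boot, seed = seed)

  el_2b <- eligibility
  el_2b$prior_bb_source <- "admission_record_only"
  co_2b <- build_cohort(bundle, el_2b, imputation)
  co_2b <- add_cohort_covariate(co_2b, "prior_bb_dispensed",
                                co_2b$prior_bb_disp)
  eff_2b <- trial_effect(co_2b, bundle, "itt", outcome_kind,
                         spline = spline, horizon = horizon,
                         n_boot = n_boot, seed = seed)
  list(prior_bb_included = eff_2a, prior_bb_admission_only = eff_2b)
}

#' Missing-data sensitivity variants
#'
#' Re-runs the intention-to-treat pipeline under complete-case deletion
#' (3a) and under the missing-category strategy (3b, continuous
#' covariates binned into quintiles plus a "missing" level).
#'
#' @inheritParams prior_bb_variants
#' @return named list of `effect_estimates` (`complete_case`,
#'   `missing_category`).
#' @export
missingness_variants <- function(bundle,
                                 eligibility = eligibility_config(),
                                 outcome_kind = "composite",
                                 spline = spline_spec(), horizon = 60L,
                                 n_boot = 0L, seed = 1L) {
  out <- list()
  for (strat in c("complete_case", "missing_category")) {
    co <- build_cohort(bundle, eligibility, strat)
    if (!nrow(co))
      stop("complete-case cohort is empty", call. = FALSE)
    out[[strat]] <- trial_effect(co, bundle, "itt", outcome_kind,
                                 spline = spline, horizon = horizon,
                                 n_boot = n_boot, seed = seed)
  }
  out
}

#' 90-day-gap per-protocol variant
#'
#' Re-runs the per-protocol pipeline with the refill gap reduced from 180
#' to 90 days.
#'
#' @param subjects imputed cohort; @param bundle registry.
#' @param gap_days reduced gap (default 90).
#' @param outcome_kind,spline,horizon,n_boot,seed analysis settings.
#' @return `effect_estimates`.
#' @export
pp_gap_variant <- function(subjects, bundle, gap_days = 90L,
                           outcome_kind = "composite",
                           spline = spline_spec(), horizon = 60L,
                           n_boot = 0L, seed = 1L) {
  trial_effect(subjects, bundle, "pp", outcome_kind,
               adherence = adherence_config(gap_days = gap_days),
               spline = spline, horizon = horizon, n_boot = n_boot,
               seed = seed)
}

#' Clone-censor-weight analysis of baseline alignment
#'
#' Sets time zero at the angiography date and assigns every eligible
#' person to both strategies (two clones).  The beta-blocker clone is
#' censored at `grace_days` if no beta-blocker dispensation has occurred
#' by then; the no-beta-blocker clone is censored at the first
#' beta-blocker dispensation.  Inverse-probability-of-censoring weights
#' for the grace window are estimated per arm from baseline covariates.
#' Events inside the assignment window now count.  Eligibility is
#' evaluated at angiography, dropping the two criteria that are only
#' observable later (statin/antithrombotic at day 30; event-free window).
#' Follow-up runs one grace interval past the usual horizon so the risk
#' horizon matches the landmark analysis's five years.
#'
#' @param bundle a `registry_bundle`.
#' @param eligibility an [eligibility_config()].
#' @param grace_days grace period for initiation (default 30).
#' @param weighting `"ip"` (grace-window censoring weights estimated from
#'   baseline covariates) or `"none"`.
#' @param time `"spline"` or `"saturated"` hazards.
#' @param spline,horizon,imputation analysis settings.
#' @return `effect_estimates` with clone bookkeeping in attribute
#'   `"clones"`.
#' @export
clone_censor_analysis <- function(bundle,
                                  eligibility = eligibility_config(),
                                  grace_days = 30L,
                                  weighting = c("ip", "none"),
                                  time = c("spline", "saturated"),
                                  spline = spline_spec(),
                                  horizon = 60L, imputation = "median") {
  weighting <- match.arg(weighting)
  time <- match.arg(time)
  masks <- eligibility_masks(bundle, eligibility)
  eligible <- masks[index_mi_angio & no_contraindication &
                      no_bb_indication & no_compliance_exclusion,
                    person_id]
  base <- assign_arm(bundle, eligible, eligibility)
  base <- impute_baseline(base, imputation)
  info <- attr(base, "covinfo")

  # observed initiation: first beta-blocker dispensation after angiography
  bb <- bundle$dispensations[drug_class %in% BB_DRUGS &
                               person_id %in% eligible]
  ang <- setNames(as.numeric(base$angio_date), base$person_id)
  bb <- bb[, .(person_id, d = as.numeric(dispense_date) -
                 ang[as.character(person_id)])]
  first_bb <- bb[d > 0, .(init_day = min(d, Inf)), by = person_id]
  base <- merge(base, first_bb, by = "person_id", all.x = TRUE)
  setattr(base, "covinfo", info)
  init_in_grace <- !is.na(base$init_day) & base$init_day <= grace_days
  if (!any(init_in_grace))
    stop("grace period of ", grace_days, " days leaves the initiation ",
         "arm empty: no one initiates in time", call. = FALSE)

  clone_subjects <- function(a) {
    s <- copy(base)
    s[, time_zero := angio_date]
    s[, arm := a]
    setattr(s, "covinfo", info)
    s
  }
  H <- as.integer(horizon) + as.integer(ceiling(grace_days / MONTH_DAYS))

  # beta-blocker clones: censored at end of grace without initiation
  s_bb <- clone_subjects("beta_blocker")
  cens_bb <- data.table(
    person_id = s_bb$person_id,
    censor_date = fifelse(init_in_grace, as.Date(NA),
                          s_bb$angio_date + grace_days))
  f_bb <- expand_person_time(s_bb, bundle, censor_dates = cens_bb,
                             outcome_kind = "composite",
                             horizon_months = H)
  # no-beta-blocker clones: censored at first initiation, whenever
  s_nb <- clone_subjects("no_beta_blocker")
  cens_nb <- data.table(
    person_id = s_nb$person_id,
    censor_date = s_nb$angio_date +
      fifelse(is.na(s_nb$init_day), NA_real_, s_nb$init_day))
  f_nb <- expand_person_time(s_nb, bundle, censor_dates = cens_nb,
                             outcome_kind = "composite",
                             horizon_months = H)
  stopifnot(all(init_in_grace |
                  is.na(cens_nb$censor_date) |
                  as.numeric(cens_nb$censor_date - s_nb$angio_date) > 0))

  frame <- rbind(f_bb, f_nb)
  if (!any(frame$arm == "beta_blocker"))
    stop("grace period leaves the initiation arm empty", call. = FALSE)

  w <- NULL
  if (weighting == "ip") {
    # one-shot grace-window censoring model per arm on baseline covariates
    grace_weight <- function(uncensored) {
      dat <- prep_model_data(base[, c("person_id", info$names),
                                  with = FALSE], info$names)
      set(dat, j = "unc", value = as.integer(uncensored))
      f <- as.formula(paste("unc ~", paste(info$names, collapse = " + ")))
      fit <- suppressWarnings(glm(f, family = binomial(), data = dat,
                                  control = list(maxit = 100L)))
      p <- predict(fit, dat, type = "response")
      mean(uncensored) / p
    }
    w_bb <- grace_weight(init_in_grace)
    # no-BB clone survives the grace window unless initiation within it
    w_nb <- grace_weight(!init_in_grace)
    wtab <- rbind(
      data.table(arm = "beta_blocker", person_id = base$person_id,
                 gw = w_bb),
      data.table(arm = "no_beta_blocker", person_id = base$person_id,
                 gw = w_nb))
    w <- wtab[frame[, .(arm, person_id)], on = c("arm", "person_id"), gw]
  }

  model <- fit_pooled_logistic(frame, weights = w, spline = spline,
                               time = time)
  hmax <- min(H, model$max_t)
  curves <- risk_curves(model, horizon = hmax)
  eff <- effect_estimates(curves, frame = frame, weights = w,
                          horizons = numeric(), spline = spline)
  attr(eff, "curves") <- curves
  attr(eff, "clones") <- list(
    n_persons = nrow(base), n_clones = 2L * nrow(base),
    bb_censored_at_grace = sum(!init_in_grace),
    nb_censored = sum(!is.na(cens_nb$censor_date)))
  attr(eff, "contrast") <- "clone_censor"
  eff
}

#' Run the full sensitivity grid
#'
#' Main ITT and per-protocol analyses plus every sensitivity variant:
#' covariate adjustment (1), prior-beta-blocker eligibility variants
#' (2a/2b), missing-data variants (3a/3b), clone-censor baseline
#' alignment (4) and the 90-day per-protocol gap.  Each entry records its
#' configuration delta from the main analysis.
#'
#' @param bundle a `registry_bundle`.
#' @param eligibility,adherence,spline configuration objects.
#' @param outcome_kind outcome analyzed across the grid.
#' @param horizon,n_boot,seed analysis settings.
#' @return object of class `sensitivity_grid`: `table` (variant label,
#'   config delta, risks, RD, RR) and `estimates` (named list).
#' @export
sensitivity_grid <- function(bundle, eligibility = eligibility_config(),
                             adherence = adherence_config(),
                             spline = spline_spec(),
                             outcome_kind = "composite", horizon = 60L,
                             n_boot = 0L, seed = 1L) {
  subjects <- build_cohort(bundle, eligibility)
  ests <- list()
  deltas <- c(
    main_itt = "none (main intention-to-treat)",
    main_pp = "none (main per-protocol)",
    covariate_adjusted = "1: baseline covariates in outcome model, no IP weights",
    prior_bb_included = "2a: prior beta-blocker users eligible; prior-use covariate",
    prior_bb_admission_only = "2b: prior use from admission record only",
    complete_case = "3a: complete-case analysis",
    missing_category = "3b: continuous covariates categorized + missing level",
    clone_censor = "4: cloning at angiography with 30-day grace",
    pp_gap90 = "per-protocol gap 90 days instead of 180")

  ests$main_itt <- trial_effect(subjects, bundle, "itt", outcome_kind,
                                spline = spline, horizon = horizon,
                                n_boot = n_boot, seed = seed)
  ests$main_pp <- trial_effect(subjects, bundle, "pp", outcome_kind,
                               adherence = adherence, spline = spline,
                               horizon = horizon, n_boot = n_boot,
                               seed = seed)
  ests$covariate_adjusted <- covariate_adjusted_analysis(
    subjects, bundle, outcome_kind, spline, horizon, n_boot, seed)
  ests <- c(ests, prior_bb_variants(bundle, eligibility, outcome_kind,
                                    spline, horizon, n_boot, seed))
  ests <- c(ests, missingness_variants(bundle, eligibility, outcome_kind,
                                       spline, horizon, n_boot, seed))
  ests$clone_censor <- clone_censor_analysis(bundle, eligibility,
                                             spline = spline,
                                             horizon = horizon)
  ests$pp_gap90 <- pp_gap_variant(subjects, bundle, 90L, outcome_kind,
                                  spline, horizon, n_boot, seed)

  tab <- rbindlist(lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    data.table(variant = nm, config_delta = deltas[[nm]],
               risk_beta_blocker = e$risks[["beta_blocker"]],
               risk_no_beta_blocker = e$risks[["no_beta_blocker"]],
               rd = e$rd, rr = e$rr)
  }))
  out <- list(table = tab, estimates = ests,
              config_hash = bundle$meta$config_hash)
  class(out) <- "sensitivity_grid"
  out
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("Sensitivity grid (composite outcome unless noted)\n")
  print(x$table, digits = 3)
  invisible(x)
}
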