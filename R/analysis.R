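#' Build the eligible, arm-assigned, imputed cohort
#'
#' Convenience wrapper: eligibility filters, prescription-based arm
#' assignment and baseline imputation in one step.
#'
#' @param bundle a `registry_bundle`.
#' @param eligibility an [eligibility_config()].
#' @param imputation imputation strategy, see [impute_baseline()].
#' @param discharge_offset_days see [assign_arm()].
#' @return imputed cohort with attributes `"flowchart"` and `"covinfo"`.
#' @export
build_cohort <- function(bundle, eligibility = eligibility_config(),
                         imputation = c("median", "complete_case",
                                        "missing_category"),
                         discharge_offset_days = 3L) {
  imputation <- match.arg(imputation)
  el <- apply_eligibility(bundle, eligibility)
  subjects <- assign_arm(bundle, el$eligible, eligibility,
                         discharge_offset_days)
  subjects <- impute_baseline(subjects, imputation)
  setattr(subjects, "flowchart", el$flowchart)
  subjects
}

# One weighted pooled-logistic analysis of a prepared person-interval
# frame.  `freq` carries bootstrap multiplicities; weight models and the
# outcome fit all honour it.
pl_analysis <- function(subjects, frame, contrast = "itt",
                        weighting = c("ip", "none", "covariate_adjusted"),
                        time = c("spline", "saturated"),
                        spline = spline_spec(), horizon = 60L,
                        hr_horizons = c(36, 48, 60), covariates = NULL,
                        truncation = NULL, freq = NULL) {
  weighting <- match.arg(weighting)
  time <- match.arg(time)
  frq <- freq %||% rep(1L, nrow(subjects))
  frq_row <- frq[match(frame$person_id, subjects$person_id)]

  bw <- cw <- NULL
  extra <- NULL
  if (weighting == "ip") {
    bw <- baseline_ip_weights(subjects, covariates, freq = freq)
    if (contrast == "pp")
      cw <- censoring_ip_weights(frame, subjects, spline = spline,
                                 freq = freq)
  } else if (weighting == "covariate_adjusted") {
    extra <- covariates %||% attr(subjects, "covinfo")$names
  }
  ipw <- as.numeric(combine_weights(frame, bw, cw, truncation))
  w <- ipw * frq_row
  use_w <- if (weighting == "none" && is.null(freq)) NULL else w

  model <- fit_pooled_logistic(frame, weights = use_w, spline = spline,
                               interaction = TRUE,
                               extra_covariates = extra,
                               subjects = subjects, time = time)
  horizon <- min(horizon, model$max_t)
  curves <- risk_curves(model, horizon = horizon)
  eff <- effect_estimates(curves, frame = frame, weights = use_w,
                          horizons = hr_horizons[hr_horizons <= horizon],
                          spline = spline, extra_covariates = extra,
                          subjects = subjects)
  attr(eff, "curves") <- curves
  attr(eff, "baseline_weights") <- bw
  eff
}

#' Estimate one intention-to-treat or per-protocol effect
#'
#' Expands the cohort into person-intervals for the requested outcome,
#' estimates the IP-weighted pooled logistic model, and (optionally)
#' bootstrap percentile confidence intervals.  Per-protocol analyses
#' censor at the non-adherence date from [nonadherence_date()] and apply
#' time-varying censoring weights on top of the baseline treatment
#' weights.  Weight models are re-estimated inside every bootstrap
#' replicate.
#'
#' @param subjects imputed cohort from [build_cohort()].
#' @param bundle the `registry_bundle`.
#' @param contrast `"itt"` or `"pp"`.
#' @param outcome_kind `"composite"`, `"death"` or `"mi"`.
#' @param adherence an [adherence_config()] (per-protocol only).
#' @param weighting `"ip"`, `"none"` (crude) or `"covariate_adjusted"`
#'   (baseline covariates in the outcome model, g-formula
#'   standardization).
#' @param time `"spline"` or `"saturated"` hazards.
#' @param spline,horizon,hr_horizons model settings.
#' @param total_effect MI analyzed under the total-effect convention.
#' @param covariates covariate set for the weight/outcome models.
#' @param truncation optional weight-truncation percentile.
#' @param n_boot bootstrap samples (0 = none).
#' @param seed bootstrap seed.
#' @param admin_end administrative end of data.
#' @return `effect_estimates` with CIs (`ci_lower`/`ci_upper`) when
#'   bootstrapped; risk curves in attribute `"curves"`.
#' @export
trial_effect <- function(subjects, bundle, contrast = c("itt", "pp"),
                         outcome_kind = "composite",
                         adherence = adherence_config(),
                         weighting = "ip", time = "spline",
                         spline = spline_spec(), horizon = 60L,
                         hr_horizons = c(36, 48, 60), total_effect = TRUE,
                         covariates = NULL, truncation = NULL,
                         n_boot = 0L, seed = 1L, admin_end = NULL) {
  contrast <- match.arg(contrast)
  censor <- NULL
  if (contrast == "pp")
    censor <- nonadherence_date(subjects, bundle, adherence)
  frame <- expand_person_time(subjects, bundle, censor_dates = censor,
                              outcome_kind = outcome_kind,
                              total_effect = total_effect,
                              horizon_months = horizon,
                              admin_end = admin_end)
  eff <- pl_analysis(subjects, frame, contrast, weighting, time, spline,
                     horizon, hr_horizons, covariates, truncation)
  if (n_boot > 0L) {
    stat <- function(s, freq) {
      as.vector(pl_analysis(s, frame, contrast, weighting, time, spline,
                            horizon, hr_horizons, covariates, truncation,
                            freq = freq))
    }
    bs <- bootstrap_cis(stat, subjects, n_boot = n_boot, seed = seed)
    eff$ci_lower <- bs$lower
    eff$ci_upper <- bs$upper
    eff$n_boot <- n_boot
    eff$n_failed <- bs$n_failed
    eff$seed <- as.integer(seed)
  }
  attr(eff, "contrast") <- contrast
  attr(eff, "outcome_kind") <- outcome_kind
  eff
}

#' Arm-specific adherence proportions
#'
#' Fraction of each arm never artificially censored before the end of
#' their (intention-to-treat) follow-up for the composite outcome.
#'
#' @param subjects cohort; @param bundle registry;
#' @param adherence an [adherence_config()].
#' @param horizon,admin_end follow-up limits.
#' @return named vector of adherence proportions by arm.
#' @export
adherence_proportions <- function(subjects, bundle,
                                  adherence = adherence_config(),
                                  horizon = 60L, admin_end = NULL) {
  censor <- nonadherence_date(subjects, bundle, adherence)
  itt <- expand_person_time(subjects, bundle, censor_dates = NULL,
                            outcome_kind = "composite",
                            horizon_months = horizon,
                            admin_end = admin_end)
  fu <- itt[, .(n_itt = max(t)), by = person_id]
  d <- merge(subjects[, .(person_id, arm, time_zero)], censor,
             by = "person_id")
  d <- merge(d, fu, by = "person_id", all.x = TRUE)
  d[is.na(n_itt), n_itt := 0L]
  cens_day <- as.numeric(d$censor_date) - as.numeric(d$time_zero)
  cens_int <- rep(Inf, length(cens_day))
  ok <- !is.na(cens_day)
  cens_int[ok] <- complete_intervals(cens_day[ok]) + 1
  d[, adherent := cens_int > n_itt]
  props <- d[, .(adherence = mean(adherent)), by = arm]
  setNames(props$adherence, props$arm)
}

#' Run the full trial emulation on a registry bundle
#'
#' Cohort construction, balance diagnostics, and intention-to-treat and
#' per-protocol effect estimation for the composite outcome and its
#' components, with optional bootstrap confidence intervals.
#'
#' @param bundle a `registry_bundle`.
#' @param eligibility,adherence,spline configuration objects.
#' @param imputation baseline imputation strategy.
#' @param outcome_kinds outcomes to analyze.
#' @param contrasts `"itt"`, `"pp"` or both.
#' @param n_boot,seed bootstrap settings (per analysis).
#' @param horizon,hr_horizons follow-up and hazard-ratio horizons.
#' @param truncation optional weight-truncation percentile.
#' @return object of class `trial_emulation`: cohort, flowchart, balance
#'   table, adherence proportions, and per contrast/outcome
#'   `effect_estimates`.
#' @export
emulate_trial <- function(bundle, eligibility = eligibility_config(),
                          adherence = adherence_config(),
                          spline = spline_spec(),
                          imputation = "median",
                          outcome_kinds = c("composite", "death", "mi"),
                          contrasts = c("itt", "pp"),
                          n_boot = 0L, seed = 1L, horizon = 60L,
                          hr_horizons = c(36, 48, 60), truncation = NULL) {
  subjects <- build_cohort(bundle, eligibility, imputation)
  bw <- baseline_ip_weights(subjects)
  balance <- balance_table(subjects, bw)
  results <- list()
  for (ctr in contrasts) {
    for (oc in outcome_kinds) {
      results[[ctr]][[oc]] <- trial_effect(
        subjects, bundle, contrast = ctr, outcome_kind = oc,
        adherence = adherence, spline = spline, horizon = horizon,
        hr_horizons = hr_horizons, truncation = truncation,
        n_boot = n_boot, seed = seed)
    }
  }
  out <- list(
    subjects = subjects,
    flowchart = attr(subjects, "flowchart"),
    balance = balance,
    weight_stats = bw$stats,
    adherence = adherence_proportions(subjects, bundle, adherence,
                                      horizon = horizon),
    results = results,
    config_hash = bundle$meta$config_hash,
    seed = as.integer(seed)
  )
  class(out) <- "trial_emulation"
  out
}

#' @export
print.trial_emulation <- function(x, ...) {
  cat("Target trial emulation: beta blockers vs no beta blockers\n")
  cat("eligible n =", nrow(x$subjects), "; adherence:",
      paste(sprintf("%s %.0f%%", names(x$adherence), 100 * x$adherence),
            collapse = ", "), "\n\n")
  for (ctr in names(x$results)) {
    cat("==", toupper(ctr), "==\n")
    for (oc in names(x$results[[ctr]])) {
      cat("--", oc, "--\n")
      print(x$results[[ctr]][[oc]])
    }
  }
  invisible(x)
}
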