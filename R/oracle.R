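#' Counterfactual oracle: true marginal risks under each strategy
#'
#' Simulates, for each of `n_oracle` persons, both counterfactual event
#' histories — always treated from time zero and never treated — from the
#' same event model as [generate_registry()], with adherence forced perfect
#' and no artificial or administrative censoring.  Common random numbers
#' are used across the two arms, so arm contrasts have smaller Monte-Carlo
#' error than the reported per-risk binomial standard errors suggest.
#'
#' @param config a [generator_config()]; only the covariate and event
#'   models matter.
#' @param n_oracle number of simulated persons (>= 1000).
#' @param seed seed for the oracle simulation (independent of the registry
#'   seed).
#' @return object of class `true_effect_oracle`: `risks` (outcome, arm, t,
#'   risk, mc_se), `effects` (outcome, true risks / RD / RR at the
#'   horizon), `n_oracle`.
#' @export
compute_true_effects <- function(config, n_oracle = 50000L, seed = 1L) {
  validate_generator_config(config)
  if (n_oracle < 1000L)
    stop("configuration error: 'n_oracle' must be at least 1000",
         call. = FALSE)
  info <- covariate_info(config$covariates)
  H <- config$horizon_months
  n <- as.integer(n_oracle)

  withr::with_seed(as.integer(seed), {
    X <- draw_covariates(config$covariates, n)
    prior_bb <- as.integer(runif(n) < config$prior_bb_fraction)
    renal_int <- draw_geom_interval(n, config$renal_onset_rate)
    R <- outer(ifelse(is.na(renal_int), Inf, as.numeric(renal_int)),
               seq_len(H), `<=`) * 1
    U_death <- matrix(runif(n * H), n, H)
    U_mi <- matrix(runif(n * H), n, H)
  })

  one_arm <- function(treated) {
    Tmat <- matrix(as.numeric(treated), n, H)
    death_int <- draw_event_interval(config$events$death, X, info, prior_bb,
                                     R, Tmat, H, U = U_death)
    mi_int <- draw_event_interval(config$events$mi, X, info, prior_bb,
                                  R, Tmat, H, U = U_mi)
    mi_int[!is.na(mi_int) & !is.na(death_int) & mi_int > death_int] <-
      NA_integer_
    list(death = death_int, mi = mi_int,
         composite = pmin(death_int, mi_int, na.rm = TRUE))
  }
  arms <- list(beta_blocker = one_arm(TRUE), no_beta_blocker = one_arm(FALSE))

  risk_curve_of <- function(evt_int) {
    cnt <- tabulate(evt_int[!is.na(evt_int)], nbins = H)
    cumsum(cnt) / n
  }
  risks <- rbindlist(lapply(names(arms), function(a) {
    rbindlist(lapply(c("composite", "death", "mi"), function(oc) {
      r <- risk_curve_of(arms[[a]][[oc]])
      data.table(outcome = oc, arm = a, t = seq_len(H), risk = r,
                 mc_se = sqrt(pmax(r * (1 - r), 0) / n))
    }))
  }))

  effects <- risks[t == H,
                   .(risk_treated = risk[arm == "beta_blocker"],
                     risk_control = risk[arm == "no_beta_blocker"],
                     mc_se_treated = mc_se[arm == "beta_blocker"],
                     mc_se_control = mc_se[arm == "no_beta_blocker"]),
                   by = outcome]
  effects[, `:=`(true_rd_5y = risk_treated - risk_control,
                 true_rr_5y = risk_treated / risk_control)]

  out <- list(risks = risks, effects = effects, n_oracle = n,
              horizon = H, seed = as.integer(seed))
  class(out) <- "true_effect_oracle"
  out
}

#' @export
print.true_effect_oracle <- function(x, ...) {
  cat("Counterfactual oracle (n =", x$n_oracle, ", horizon =", x$horizon,
      "months)\n")
  print(x$effects[, .(outcome, risk_treated, risk_control, true_rd_5y,
                      true_rr_5y)], digits = 4)
  invisible(x)
}
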