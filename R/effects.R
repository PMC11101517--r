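#' Risk difference and ratio for a pair of risks
#'
#' @param risk_treated,risk_control absolute risks (proportions).
#' @return named vector: `rd` (treated minus control) and `rr`.
#' @export
risk_contrast <- function(risk_treated, risk_control) {
  rr <- if (risk_control > 0) risk_treated / risk_control else NA_real_
  c(rd = risk_treated - risk_control, rr = rr)
}

#' Effect estimates: 5-year risks, RD, RR and average hazard ratios
#'
#' Risks, the risk difference and the risk ratio at the final horizon come
#' from the fitted risk curves.  The average hazard ratio at each horizon
#' is `exp` of the strategy coefficient from a pooled logistic refit
#' *without* the strategy-by-time product term on person-time truncated at
#' that horizon (the discrete-time analogue of a Cox hazard ratio).
#'
#' @param curves a `risk_curve` pair from [risk_curves()].
#' @param frame,weights person-interval data and per-row weights used to
#'   refit the no-interaction models; omit to skip hazard ratios.
#' @param horizons months at which average hazard ratios are reported.
#' @param spline,extra_covariates,subjects passed to the refits.
#' @return object of class `effect_estimates`.
#' @export
effect_estimates <- function(curves, frame = NULL, weights = NULL,
                             horizons = c(36, 48, 60),
                             spline = spline_spec(),
                             extra_covariates = NULL, subjects = NULL) {
  tmax <- max(curves$t)
  risks <- curves[t == tmax, setNames(risk, arm)]
  ctr <- risk_contrast(risks[["beta_blocker"]], risks[["no_beta_blocker"]])
  if (is.na(ctr[["rr"]]))
    warning("risk ratio undefined: control risk is zero")

  hr <- if (length(horizons))
    setNames(rep(NA_real_, length(horizons)), paste0("hr_", horizons))
  else setNames(numeric(), character())
  events <- c(beta_blocker = NA_real_, no_beta_blocker = NA_real_)
  if (!is.null(frame)) {
    w <- weights %||% rep(1, nrow(frame))
    ev <- data.table(arm = frame$arm,
                     event = frame$event)[, .(n = sum(event)), by = arm]
    events <- setNames(as.numeric(ev$n), ev$arm)[names(events)]
    for (i in seq_along(horizons)) {
      h <- horizons[i]
      sel <- frame$t <= h
      sub <- frame[sel]
      if (sum(sub$event) == 0L) next
      fit <- fit_pooled_logistic(sub, weights = w[sel], spline = spline,
                                 interaction = FALSE,
                                 extra_covariates = extra_covariates,
                                 subjects = subjects)
      hr[i] <- exp(coef(fit$fit)[["arm01"]])
    }
  }
  out <- list(risks = risks, rd = unname(ctr[["rd"]]),
              rr = unname(ctr[["rr"]]), hr = hr, events = events,
              horizon = tmax)
  class(out) <- "effect_estimates"
  out
}

#' Flatten effect estimates to a named numeric vector
#'
#' @param x an `effect_estimates` object.
#' @param ... unused.
#' @return named numeric vector (risks, rd, rr, hr_*).
#' @export
as.vector.effect_estimates <- function(x, ...) {
  c(risk_beta_blocker = unname(x$risks[["beta_blocker"]]),
    risk_no_beta_blocker = unname(x$risks[["no_beta_blocker"]]),
    rd = x$rd, rr = x$rr, x$hr)
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("%d-month risks: %.1f%% (beta blockers) vs %.1f%% (no beta blockers)\n",
              x$horizon, 100 * x$risks[["beta_blocker"]],
              100 * x$risks[["no_beta_blocker"]]))
  cat(sprintf("risk difference: %.1f points; risk ratio: %.2f\n",
              100 * x$rd, x$rr))
  hrs <- x$hr[!is.na(x$hr)]
  if (length(hrs))
    cat("average hazard ratios:",
        paste(sprintf("%s = %.2f", sub("hr_", "", names(hrs)), hrs),
              collapse = ", "), "\n")
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples persons (the resampling unit is the person with all their
#' records) by drawing multinomial frequency weights, re-runs the full
#' analysis closure on each replicate, and returns percentile 2.5/97.5
#' intervals.  Replicates whose analysis fails are dropped and counted; an
#' error is raised if more than 5\% fail.
#'
#' @param statistic function `(subjects, freq)` returning a named numeric
#'   vector of point estimates; `freq` is a per-subject resampling
#'   multiplicity (so weight-model and outcome-model fits inside the
#'   closure must honour it).
#' @param subjects the cohort to resample.
#' @param n_boot number of bootstrap samples (paper-scale default 500).
#' @param seed integer seed; results are deterministic given it.
#' @param level confidence level.
#' @return list: `estimate` (full-sample statistic), `lower`, `upper`,
#'   `n_boot`, `n_failed`, `replicates` (matrix).
#' @export
bootstrap_cis <- function(statistic, subjects, n_boot = 500L, seed = 1L,
                          level = 0.95) {
  if (n_boot < 2L)
    stop("configuration error: 'n_boot' must be at least 2", call. = FALSE)
  n <- nrow(subjects)
  est <- statistic(subjects, rep(1L, n))
  reps <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_boot), function(b) {
      freq <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      tryCatch(statistic(subjects, freq), error = function(e) NULL)
    })
  })
  failed <- vapply(reps, is.null, TRUE)
  if (mean(failed) > 0.05)
    stop("bootstrap error: ", sum(failed), " of ", n_boot,
         " replicates failed (> 5%)", call. = FALSE)
  mat <- do.call(rbind, reps[!failed])
  alpha <- (1 - level) / 2
  qs <- apply(mat, 2L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE,
              names = FALSE)
  list(estimate = est, lower = setNames(qs[1L, ], colnames(mat)),
       upper = setNames(qs[2L, ], colnames(mat)), n_boot = n_boot,
       n_failed = sum(failed), replicates = mat)
}
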