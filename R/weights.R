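# Prepare a model frame: categorical covariates become factors with the
# most frequent level as reference; binary/continuous stay numeric.
prep_model_data <- function(dat, covariates) {
  out <- copy(dat)
  for (nm in covariates) {
    v <- out[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      ref <- names(sort(table(v), decreasing = TRUE))[1L]
      set(out, j = nm,
          value = factor(v, levels = c(ref, setdiff(sort(unique(v)), ref))))
    }
  }
  out
}

check_glm_fit <- function(fit, what) {
  if (!fit$converged)
    stop("estimation error: ", what, " model did not converge", call. = FALSE)
  cf <- coef(fit)
  big <- names(cf)[!is.na(cf) & abs(cf) > 15]
  if (length(big))
    stop("estimation error: ", what, " model shows separation in: ",
         paste(big, collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Stabilized baseline inverse-probability-of-treatment weights
#'
#' Fits a logistic regression of treatment assignment on baseline
#' covariates and returns stabilized weights
#' `P(arm = a) / P(arm = a | covariates)` evaluated at each subject's own
#' arm.  With no confounding these weights are 1 on average; their mean is
#' always close to 1 by construction.
#'
#' @param subjects imputed cohort from [impute_baseline()].
#' @param covariates names of baseline covariates for the assignment
#'   model; defaults to all covariates recorded in the cohort's
#'   `"covinfo"` attribute.
#' @param freq optional per-subject frequency weights (bootstrap
#'   multiplicities).
#' @return object of class `weight_set`: `baseline` (person_id, sw),
#'   `model` (coefficients), `stats` (min/mean/max).
#' @export
baseline_ip_weights <- function(subjects, covariates = NULL, freq = NULL) {
  info <- attr(subjects, "covinfo")
  covariates <- covariates %||% info$names
  a <- as.integer(subjects$arm == "beta_blocker")
  if (all(a == 1L) || all(a == 0L))
    stop("positivity error: an arm is empty", call. = FALSE)
  dat <- prep_model_data(subjects[, c("person_id", covariates),
                                  with = FALSE], covariates)
  if (anyNA(dat[, covariates, with = FALSE]))
    stop("estimation error: covariates contain missing values; impute first",
         call. = FALSE)
  set(dat, j = "arm01", value = a)
  frq <- freq %||% rep(1, nrow(dat))
  if (all(a[frq > 0] == 1L) || all(a[frq > 0] == 0L))
    stop("positivity error: an arm is empty", call. = FALSE)
  f <- as.formula(paste("arm01 ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(f, family = binomial(), data = dat,
                              weights = frq))
  check_glm_fit(fit, "treatment-assignment")
  p1 <- predict(fit, dat, type = "response")
  marg <- weighted.mean(a, frq)
  sw <- ifelse(a == 1L, marg / p1, (1 - marg) / (1 - p1))
  out <- list(
    baseline = data.table(person_id = subjects$person_id, sw = sw),
    model = summary(fit)$coefficients,
    stats = c(min = min(sw), mean = mean(sw), max = max(sw))
  )
  class(out) <- "weight_set"
  out
}

#' Time-varying inverse-probability-of-censoring weights
#'
#' For the per-protocol analysis: within each arm, fits pooled logistic
#' models for being artificially censored in each interval.  The
#' denominator model conditions on baseline covariates, the time-varying
#' covariates and a restricted cubic spline of interval; the numerator
#' (stabilizing) model drops the time-varying covariates.  The cumulative
#' weight at interval `t` is the product over `s <= t` of
#' `(1 - p_num(s)) / (1 - p_den(s))`.
#'
#' @param frame person-interval data from [expand_person_time()] with a
#'   `"censor_frame"` attribute (i.e., expanded with censor dates).
#' @param subjects imputed cohort (baseline covariates).
#' @param baseline_covariates,tv_covariates model covariates; defaults:
#'   all baseline covariates, and renal disease plus the six
#'   co-medication classes.
#' @param spline a [spline_spec()] for the time trend.
#' @param freq optional per-subject frequency weights (bootstrap
#'   multiplicities).
#' @return object of class `weight_set` with `interval`
#'   (person_id, t, cw) and per-arm model summaries.
#' @export
censoring_ip_weights <- function(frame, subjects,
                                 baseline_covariates = NULL,
                                 tv_covariates = c("renal", COMED_CLASSES),
                                 spline = spline_spec(), freq = NULL) {
  cf <- attr(frame, "censor_frame")
  if (is.null(cf))
    stop("'frame' carries no censoring information; expand with censor dates",
         call. = FALSE)
  info <- attr(subjects, "covinfo")
  baseline_covariates <- baseline_covariates %||% info$names
  dat <- prep_model_data(subjects[, c("person_id", baseline_covariates),
                                  with = FALSE], baseline_covariates)
  cf <- merge(cf, dat, by = "person_id")
  cf <- add_rcs_columns(cf, spline)
  rcs_cols <- attr(cf, "rcs_cols")

  models <- list()
  parts <- vector("list", 2L)
  arms <- c("beta_blocker", "no_beta_blocker")
  for (i in seq_along(arms)) {
    a <- arms[i]
    da <- cf[arm == a]
    frq <- if (is.null(freq)) rep(1, nrow(da)) else
      freq[match(da$person_id, subjects$person_id)]
    risk_rows <- frame[arm == a, .(person_id, t)]
    if (!nrow(da) || sum(da$cens * frq) == 0) {
      message("no artificial censoring in arm '", a,
              "'; censoring weights set to 1")
      parts[[i]] <- risk_rows[, .(person_id, t, cw = 1)]
      next
    }
    f_den <- as.formula(paste("cens ~",
                              paste(c(baseline_covariates, tv_covariates,
                                      rcs_cols), collapse = " + ")))
    f_num <- as.formula(paste("cens ~",
                              paste(c(baseline_covariates, rcs_cols),
                                    collapse = " + ")))
    fit_den <- suppressWarnings(glm(f_den, family = binomial(), data = da,
                                    weights = frq,
                                    control = list(maxit = 100L)))
    fit_num <- suppressWarnings(glm(f_num, family = binomial(), data = da,
                                    weights = frq,
                                    control = list(maxit = 100L)))
    if (!fit_den$converged || !fit_num$converged)
      warning("censoring-weight model for arm '", a,
              "' did not fully converge; weights may be unstable")
    models[[a]] <- list(denominator = summary(fit_den)$coefficients,
                        numerator = summary(fit_num)$coefficients)
    keep <- da$cens == 0L
    w <- data.table(person_id = da$person_id[keep], t = da$t[keep],
                    p_den = predict(fit_den, da[keep], type = "response"),
                    p_num = predict(fit_num, da[keep], type = "response"))
    setorder(w, person_id, t)
    w[, cw := cumprod((1 - p_num) / (1 - p_den)), by = person_id]
    parts[[i]] <- w[, .(person_id, t, cw)]
  }
  out <- list(interval = rbindlist(parts), models = models)
  class(out) <- "weight_set"
  out
}

#' Truncate extreme weights
#'
#' Caps weights at the given upper percentile and floors them at its
#' mirror image.  `percentile = NULL` is the identity (the default
#' analysis never truncates).
#'
#' @param w numeric weight vector.
#' @param percentile upper percentile in (50, 100], or `NULL`.
#' @return the (possibly) truncated vector, with attribute `"truncation"`.
#' @export
truncate_weights <- function(w, percentile = NULL) {
  if (is.null(percentile)) {
    attr(w, "truncation") <- list(applied = FALSE)
    return(w)
  }
  if (percentile <= 50 || percentile > 100)
    stop("configuration error: 'percentile' must be in (50, 100]",
         call. = FALSE)
  hi <- quantile(w, percentile / 100, names = FALSE)
  lo <- quantile(w, 1 - percentile / 100, names = FALSE)
  out <- pmin(pmax(w, lo), hi)
  attr(out, "truncation") <- list(applied = TRUE, percentile = percentile,
                                  lower = lo, upper = hi)
  out
}

# Combined per-interval analysis weight: baseline stabilized treatment
# weight times the cumulative censoring weight; censoring weights are
# carried forward past the last censorable interval (e.g. after death in
# the total-effect MI data).
combine_weights <- function(frame, baseline = NULL, censoring = NULL,
                            truncation = NULL) {
  w <- rep(1, nrow(frame))
  if (!is.null(baseline)) {
    bw <- baseline$baseline[match(frame$person_id,
                                  baseline$baseline$person_id), sw]
    bw[is.na(bw)] <- 1
    w <- w * bw
  }
  if (!is.null(censoring)) {
    tmp <- data.table(person_id = frame$person_id, t = frame$t,
                      idx = seq_len(nrow(frame)), cw = NA_real_)
    tmp[censoring$interval, on = c("person_id", "t"), cw := i.cw]
    # carry the last available weight forward within person
    setorder(tmp, person_id, t)
    tmp[, cw := nafill(cw, type = "locf"), by = person_id]
    tmp[is.na(cw), cw := 1]
    setorder(tmp, idx)
    w <- w * tmp$cw
  }
  truncate_weights(w, truncation)
}
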