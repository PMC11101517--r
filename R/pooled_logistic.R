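#' Fit an IP-weighted pooled logistic discrete-time hazard model
#'
#' Regresses the per-interval event indicator on the assigned strategy, a
#' restricted cubic spline of follow-up time and (by default) their full
#' product term, optionally plus baseline covariates.  With
#' `time = "saturated"` the time trend is one indicator per interval and
#' the fit is computed analytically as the weighted per-(arm, interval)
#' event proportion — the exact logistic MLE on the saturated design.
#'
#' @param frame person-interval data from [expand_person_time()].
#' @param weights per-row analysis weights (combined IP weights), or
#'   `NULL`.
#' @param spline a [spline_spec()] (ignored for saturated time).
#' @param interaction include the full strategy-by-time product term.
#' @param extra_covariates baseline covariate names entered additively
#'   (requires `subjects`); used by the covariate-adjusted sensitivity
#'   analysis.
#' @param subjects cohort table supplying `extra_covariates`.
#' @param time `"spline"` or `"saturated"`.
#' @param robust also compute a person-clustered sandwich standard error
#'   for the strategy coefficient (reported for reference; inference uses
#'   the bootstrap).  Requires the sandwich package.
#' @return object of class `pooled_logistic`.
#' @export
fit_pooled_logistic <- function(frame, weights = NULL,
                                spline = spline_spec(),
                                interaction = TRUE,
                                extra_covariates = NULL, subjects = NULL,
                                time = c("spline", "saturated"),
                                robust = FALSE) {
  time <- match.arg(time)
  if (sum(frame$event) < 1L)
    stop("estimation error: no events in the person-interval data",
         call. = FALSE)
  if (!is.null(weights) && any(!is.finite(weights)))
    stop("estimation error: weights must be finite", call. = FALSE)
  w <- weights %||% rep(1, nrow(frame))
  zero_arms <- setdiff(unique(frame$arm),
                       unique(frame$arm[frame$event == 1L]))
  if (length(zero_arms))
    warning("no events in arm(s): ", paste(zero_arms, collapse = ", "))

  if (time == "saturated") {
    if (!is.null(extra_covariates))
      stop("saturated-time fits do not support extra covariates",
           call. = FALSE)
    hz <- data.table(arm = frame$arm, t = frame$t, event = frame$event,
                     w = w)[, .(at_risk = sum(w), events = sum(w * event)),
                            by = .(arm, t)]
    hz[, hazard := events / at_risk]
    setorder(hz, arm, t)
    out <- list(type = "saturated", hazards = hz,
                max_t = max(frame$t), zero_event_arms = zero_arms)
    class(out) <- "pooled_logistic"
    return(out)
  }

  if (!is.null(extra_covariates) && is.null(subjects))
    stop("'subjects' is required when 'extra_covariates' are used",
         call. = FALSE)
  dat <- data.table(event = frame$event,
                    arm01 = as.integer(frame$arm == "beta_blocker"),
                    t = as.numeric(frame$t))
  dat <- add_rcs_columns(dat, spline)
  rcs_cols <- attr(dat, "rcs_cols")
  subj_ref <- NULL
  if (!is.null(extra_covariates)) {
    subj_ref <- prep_model_data(subjects, extra_covariates)
    cols <- subj_ref[match(frame$person_id, subj_ref$person_id),
                     extra_covariates, with = FALSE]
    dat <- cbind(dat, cols)
  }
  tterm <- paste(rcs_cols, collapse = " + ")
  rhs <- if (interaction) paste0("arm01 * (", tterm, ")")
         else paste("arm01 +", tterm)
  if (!is.null(extra_covariates))
    rhs <- paste(rhs, "+", paste(extra_covariates, collapse = " + "))
  f <- as.formula(paste("event ~", rhs))
  fam <- if (is.null(weights)) binomial() else quasibinomial()
  fit <- glm(f, family = fam, data = dat, weights = w, model = robust,
             x = robust, y = robust)
  check_glm_fit(fit, "pooled logistic")
  robust_se <- NULL
  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stop("the sandwich package is required for robust = TRUE",
           call. = FALSE)
    V <- sandwich::vcovCL(fit, cluster = frame$person_id)
    robust_se <- sqrt(diag(V))
  }
  out <- list(type = "spline", fit = fit, spline = spline,
              interaction = interaction,
              extra_covariates = extra_covariates,
              subjects = subj_ref, max_t = max(frame$t),
              zero_event_arms = zero_arms, robust_se = robust_se)
  class(out) <- "pooled_logistic"
  out
}

#' @export
print.pooled_logistic <- function(x, ...) {
  cat("Pooled logistic discrete-time hazard model (", x$type, " time)\n",
      sep = "")
  if (x$type == "spline") print(coef(x$fit)) else print(head(x$hazards))
  invisible(x)
}

#' Arm-specific hazard and cumulative-risk curves
#'
#' Hazards come from the fitted model on the interval grid; cumulative
#' risk follows the product-limit recursion
#' `risk(t) = 1 - prod_{s<=t}(1 - hazard(s))`.  When the model contains
#' baseline covariates, risks are standardized over the cohort: each
#' subject's risk curve is predicted under both strategies and averaged
#' (parametric g-formula).
#'
#' @param model a `pooled_logistic` fit (spline fits must include the
#'   strategy-by-time interaction).
#' @param horizon number of intervals; must not exceed the fitted support.
#' @return data.table: arm, t, hazard, risk (class `risk_curve`).
#' @export
risk_curves <- function(model, horizon = 60L) {
  if (horizon > model$max_t)
    stop("extrapolation error: horizon ", horizon,
         " exceeds the fitted support (max interval ", model$max_t, ")",
         call. = FALSE)
  arms <- c("beta_blocker", "no_beta_blocker")
  if (model$type == "saturated") {
    grid <- CJ(arm = arms, t = seq_len(horizon))
    grid <- merge(grid, model$hazards[, .(arm, t, hazard)],
                  by = c("arm", "t"), all.x = TRUE)
    grid[is.na(hazard), hazard := 0]
    setorder(grid, arm, t)
    grid[, risk := 1 - cumprod(1 - hazard), by = arm]
    setattr(grid, "class", c("risk_curve", class(grid)))
    return(grid[])
  }
  if (!model$interaction)
    stop("risk curves require the strategy-by-time interaction",
         call. = FALSE)
  fit <- model$fit
  tgrid <- as.numeric(seq_len(horizon))
  base_nd <- function(arm01) {
    nd <- data.table(arm01 = arm01, t = tgrid)
    add_rcs_columns(nd, model$spline)
  }
  if (is.null(model$extra_covariates)) {
    out <- rbindlist(lapply(arms, function(a) {
      nd <- base_nd(as.integer(a == "beta_blocker"))
      h <- as.numeric(predict(fit, nd, type = "response"))
      data.table(arm = a, t = seq_len(horizon), hazard = h,
                 risk = 1 - cumprod(1 - h))
    }))
  } else {
    # additive covariates: per-subject linear-predictor offset trick
    subj <- model$subjects
    nd1 <- cbind(base_nd(0L),
                 subj[rep(1L, horizon), model$extra_covariates,
                      with = FALSE])
    a0 <- as.numeric(predict(fit, nd1, type = "link"))
    nd1$arm01 <- 1L
    a1 <- as.numeric(predict(fit, nd1, type = "link"))
    ndo <- cbind(data.table(arm01 = 0L, t = 1),
                 subj[, model$extra_covariates, with = FALSE])
    ndo <- add_rcs_columns(ndo, model$spline)
    o <- as.numeric(predict(fit, ndo, type = "link")) - a0[1L]
    out <- rbindlist(lapply(arms, function(a) {
      at <- if (a == "beta_blocker") a1 else a0
      H <- plogis(outer(o, at, `+`))          # subjects x t
      S <- t(apply(1 - H, 1L, cumprod))
      if (horizon == 1L) S <- matrix(S, ncol = 1L)
      data.table(arm = a, t = seq_len(horizon),
                 hazard = colMeans(H), risk = colMeans(1 - S))
    }))
  }
  setattr(out, "class", c("risk_curve", class(out)))
  out[]
}
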