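#' Assign eligible persons to a treatment strategy from dispensation data
#'
#' A person is assigned to the beta-blocker strategy if a metoprolol or
#' bisoprolol dispensation exists strictly after angiography and at or
#' before angiography + window.  If no such dispensation exists but the
#' discharge record flags a beta blocker, the assignment date is set at the
#' discharge date.  Everyone else is assigned to no beta blockers.  Time
#' zero is angiography + window for both arms (landmark alignment).
#'
#' @param bundle a `registry_bundle`.
#' @param eligible person ids from [apply_eligibility()].
#' @param config an [eligibility_config()].
#' @param discharge_offset_days discharge date = angiography + offset, used
#'   for the discharge-record fallback assignment.
#' @return data.table of eligible subjects: person_id, arm, angio_date,
#'   assignment_date, time_zero, baseline covariates, `miss_*` flags for
#'   continuous covariates, prior_bb_disp and admission_record_prior_bb
#'   indicators.  Covariate metadata is carried in attribute `"covinfo"`.
#' @export
assign_arm <- function(bundle, eligible, config = eligibility_config(),
                       discharge_offset_days = 3L) {
  p <- bundle$persons[person_id %in% eligible]
  angio <- as.integer(p$angio_date)
  t0 <- angio + config$assignment_window_days

  bb <- bundle$dispensations[drug_class %in% BB_DRUGS,
                             .(person_id, d = as.integer(dispense_date))]
  bb <- bb[p[, .(person_id, lo = angio, hi = t0)], on = "person_id",
           nomatch = NULL]
  if (config$exclude_prior_bb && config$prior_bb_source == "both" &&
      bb[d <= lo & d >= lo - config$lookback_days, .N] > 0L) {
    bad <- bb[d <= lo, unique(person_id)]
    stop("inconsistency: beta-blocker dispensation at/before angiography ",
         "for eligible person(s) ", paste(head(bad, 5L), collapse = ", "),
         " (should have been excluded upstream)", call. = FALSE)
  }
  win <- bb[d > lo & d <= hi, .(first_disp = min(d, Inf)), by = person_id]

  subjects <- data.table(
    person_id = p$person_id,
    angio_date = p$angio_date,
    time_zero = as.Date(t0, origin = "1970-01-01"),
    angio_day = angio,
    discharge = as.integer(p$discharge_bb %||% rep(0L, nrow(p))) == 1L
  )
  subjects <- merge(subjects, win, by = "person_id", all.x = TRUE)
  assign_day <- fifelse(!is.na(subjects$first_disp),
                        as.numeric(subjects$first_disp),
                        fifelse(subjects$discharge,
                                as.numeric(subjects$angio_day +
                                             discharge_offset_days),
                                NA_real_))
  subjects[, arm := fifelse(!is.na(assign_day), "beta_blocker",
                            "no_beta_blocker")]
  subjects[, assignment_date := as.Date(assign_day, origin = "1970-01-01")]
  subjects[, c("first_disp", "angio_day", "discharge") := NULL]

  # baseline covariates + missingness flags + prior-BB indicators
  info <- bundle$meta$covinfo
  covs <- p[, c("person_id", info$names), with = FALSE]
  subjects <- merge(subjects, covs, by = "person_id")
  for (nm in info$names[info$kinds == "continuous"])
    set(subjects, j = paste0("miss_", nm),
        value = as.integer(is.na(subjects[[nm]])))

  lb <- config$lookback_days
  hist <- bundle$dispensations[drug_class %in% BB_DRUGS,
                               .(person_id, d = as.integer(dispense_date))]
  hist <- hist[p[, .(person_id, lo = angio - lb, hi = angio)],
               on = "person_id", nomatch = NULL][d >= lo & d <= hi]
  subjects[, prior_bb_disp := as.integer(person_id %in% hist$person_id)]
  adm <- p[, .(person_id, admission_record_prior_bb)]
  subjects <- merge(subjects, adm, by = "person_id")

  setattr(subjects, "covinfo", info)
  setorder(subjects, person_id)
  subjects[]
}

#' Impute missing baseline covariates
#'
#' Three strategies: `median` replaces missing continuous values with the
#' cohort median of non-missing values and turns missing categorical
#' values into a `"missing"` level; `complete_case` drops subjects with any
#' missing analysis covariate; `missing_category` bins each continuous
#' covariate into quintiles plus a `"missing"` level (categoricals as under
#' `median`).
#'
#' @param subjects cohort from [assign_arm()].
#' @param strategy one of `"median"`, `"complete_case"`,
#'   `"missing_category"`.
#' @return the imputed cohort; attribute `"covinfo"` is updated when
#'   continuous covariates become categorical.
#' @export
impute_baseline <- function(subjects,
                            strategy = c("median", "complete_case",
                                         "missing_category")) {
  strategy <- match.arg(strategy)
  info <- attr(subjects, "covinfo")
  out <- copy(subjects)
  cont <- info$names[info$kinds == "continuous"]
  cats <- info$names[info$kinds == "categorical"]

  if (strategy == "complete_case") {
    keep <- complete.cases(out[, info$names, with = FALSE])
    out <- out[keep]
    setattr(out, "covinfo", info)
    return(out[])
  }

  for (nm in cats) {
    v <- out[[nm]]
    if (anyNA(v)) set(out, j = nm, value = fifelse(is.na(v), "missing", v))
  }
  if (strategy == "median") {
    for (nm in cont) {
      v <- out[[nm]]
      if (all(is.na(v)))
        stop("imputation error: all values missing for covariate '", nm,
             "'", call. = FALSE)
      set(out, j = nm, value = fifelse(is.na(v), median(v, na.rm = TRUE), v))
    }
  } else {  # missing_category: quintiles + "missing" level
    for (nm in cont) {
      v <- out[[nm]]
      qs <- quantile(v, probs = seq(0, 1, 0.2), na.rm = TRUE, names = FALSE)
      qs[1] <- -Inf; qs[length(qs)] <- Inf
      lev <- cut(v, breaks = unique(qs), labels = FALSE,
                 include.lowest = TRUE)
      set(out, j = nm, value = fifelse(is.na(v), "missing", paste0("q", lev)))
      info$kinds[[nm]] <- "categorical"
    }
  }
  setattr(out, "covinfo", info)
  out[]
}
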