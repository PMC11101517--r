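#' Eligibility configuration for the emulated trial
#'
#' Operationalizes the trial's entry criteria on registry tables:
#' contraindications to beta blockers (bradycardia, AV block II-III,
#' hypotension, syncope, asthma, COPD, stroke in the previous 3 years),
#' beta-blocker indications other than secondary prevention (prior
#' beta-blocker use, heart rate >= 120, SBP >= 180, DBP >= 120, chronic
#' heart failure, atrial flicker/flutter), conditions limiting protocol
#' compliance (psychiatric disorders, dementia), statin and antithrombotic
#' co-treatment at baseline, and freedom from death/MI during the
#' assignment window.
#'
#' @param assignment_window_days window after angiography within which a
#'   dispensation counts as assignment; time zero = angiography + window.
#' @param lookback_years diagnosis/dispensation lookback.
#' @param contraindication_codes,indication_codes,compliance_exclusion_codes
#'   symbolic condition-code sets.
#' @param heart_rate_max,sbp_max,dbp_max vital-sign thresholds at or above
#'   which a beta-blocker indication is assumed (a threshold is skipped if
#'   the covariate is absent; missing values never trigger it).
#' @param require_statin_antithrombotic require both drug classes dispensed
#'   at or before time zero within the lookback.
#' @param exclude_prior_bb exclude persons with prior beta-blocker use.
#' @param prior_bb_source `"both"` (dispensation history or admission
#'   record) or `"admission_record_only"`.
#' @return object of class `eligibility_config`.
#' @export
eligibility_config <- function(
    assignment_window_days = 30L,
    lookback_years = 3L,
    contraindication_codes = CONTRAINDICATION_CODES,
    indication_codes = INDICATION_CODES,
    compliance_exclusion_codes = COMPLIANCE_CODES,
    heart_rate_max = 120,
    sbp_max = 180,
    dbp_max = 120,
    require_statin_antithrombotic = TRUE,
    exclude_prior_bb = TRUE,
    prior_bb_source = c("both", "admission_record_only")) {
  if (assignment_window_days < 1L)
    stop("configuration error: 'assignment_window_days' must be >= 1",
         call. = FALSE)
  assert_positive(c(heart_rate_max, sbp_max, dbp_max), "vital thresholds")
  cfg <- list(
    assignment_window_days = as.integer(assignment_window_days),
    lookback_days = as.integer(round(lookback_years * 365.25)),
    contraindication_codes = contraindication_codes,
    indication_codes = indication_codes,
    compliance_exclusion_codes = compliance_exclusion_codes,
    heart_rate_max = heart_rate_max, sbp_max = sbp_max, dbp_max = dbp_max,
    require_statin_antithrombotic = require_statin_antithrombotic,
    exclude_prior_bb = exclude_prior_bb,
    prior_bb_source = match.arg(prior_bb_source)
  )
  class(cfg) <- "eligibility_config"
  cfg
}

# Per-criterion pass indicators, one column per criterion, evaluated
# independently of each other (so final membership is order-free).
eligibility_masks <- function(bundle, config) {
  p <- bundle$persons
  n <- nrow(p)
  angio <- as.integer(p$angio_date)
  index <- as.integer(p$index_date)
  t0 <- angio + config$assignment_window_days
  lb <- config$lookback_days

  dxp <- bundle$diagnoses[, .(person_id, condition_code,
                              d = as.integer(date))]
  dsp <- bundle$dispensations[, .(person_id, drug_class,
                                  d = as.integer(dispense_date))]
  ocp <- bundle$outcomes[, .(person_id, d = as.integer(date))]

  has_dx <- function(codes) {
    hits <- dxp[condition_code %in% codes]
    hits <- hits[p[, .(person_id, lo = angio - lb, hi = angio)],
                 on = "person_id", nomatch = NULL][d >= lo & d <= hi]
    p$person_id %in% hits$person_id
  }

  # (1) index MI with angiography performed within the index window
  m1 <- !is.na(p$angio_date) & !is.na(p$index_date) &
    angio >= index & angio - index <= 30L

  # (2) no contraindication diagnosis in the lookback
  m2 <- !has_dx(config$contraindication_codes)

  # (3) no beta-blocker indication: prior BB use, vitals, indication codes
  prior_disp <- dsp[drug_class %in% BB_DRUGS]
  prior_disp <- prior_disp[p[, .(person_id, lo = angio - lb, hi = angio)],
                           on = "person_id", nomatch = NULL][d >= lo & d <= hi]
  prior_bb_hist <- p$person_id %in% prior_disp$person_id
  prior_bb_flag <- as.logical(p$admission_record_prior_bb %||% rep(0L, n))
  prior_bb <- switch(config$prior_bb_source,
                     both = prior_bb_hist | prior_bb_flag,
                     admission_record_only = prior_bb_flag)
  if (!config$exclude_prior_bb) prior_bb <- rep(FALSE, n)
  vital_hit <- function(col, thr) {
    if (!col %in% names(p)) return(rep(FALSE, n))
    v <- p[[col]]
    !is.na(v) & v >= thr
  }
  m3 <- !(prior_bb |
            vital_hit("heart_rate", config$heart_rate_max) |
            vital_hit("sbp", config$sbp_max) |
            vital_hit("dbp", config$dbp_max) |
            has_dx(config$indication_codes))

  # (4) no compliance-limiting diagnosis in the lookback
  m4 <- !has_dx(config$compliance_exclusion_codes)

  # (5) statin AND antithrombotic dispensed at/before time zero, in lookback
  if (config$require_statin_antithrombotic) {
    sa <- dsp[drug_class %in% c("statin", "antithrombotic")]
    sa <- sa[p[, .(person_id, lo = angio - lb, hi = t0)],
             on = "person_id", nomatch = NULL][d >= lo & d <= hi]
    sa <- sa[, .(both = uniqueN(drug_class) == 2L), by = person_id]
    m5 <- p$person_id %in% sa[both == TRUE, person_id]
  } else {
    m5 <- rep(TRUE, n)
  }

  # (6) no death/MI at or before time zero (assignment-window events)
  ev <- ocp[p[, .(person_id, hi = t0)], on = "person_id",
            nomatch = NULL][d <= hi]
  m6 <- !(p$person_id %in% ev$person_id)

  data.table(person_id = p$person_id,
             index_mi_angio = m1, no_contraindication = m2,
             no_bb_indication = m3, no_compliance_exclusion = m4,
             statin_antithrombotic = m5, event_free_window = m6)
}

#' Apply eligibility criteria and record the selection flowchart
#'
#' Criteria are applied in a fixed declared order: (1) index MI with
#' angiography, (2) no contraindication in the lookback, (3) no
#' beta-blocker indication (prior use, vital thresholds, indication
#' diagnoses), (4) no compliance-limiting diagnosis, (5) statin and
#' antithrombotic at baseline, (6) no death/MI within the assignment
#' window.  Each criterion's pass set is computed independently, so the
#' final membership does not depend on the order, while the flowchart's
#' step counts do.
#'
#' @param bundle a `registry_bundle`.
#' @param config an [eligibility_config()].
#' @param criterion_order permutation of criteria 2..5 (flowchart display
#'   order; the final eligible set is unchanged).
#' @return list with `eligible` (person ids) and `flowchart`
#'   (data.table of criterion label and n remaining); the per-criterion
#'   masks are attached as attribute `"masks"`.
#' @export
apply_eligibility <- function(bundle, config = eligibility_config(),
                              criterion_order = c("no_contraindication",
                                                  "no_bb_indication",
                                                  "no_compliance_exclusion",
                                                  "statin_antithrombotic")) {
  stopifnot(setequal(criterion_order,
                     c("no_contraindication", "no_bb_indication",
                       "no_compliance_exclusion", "statin_antithrombotic")))
  masks <- eligibility_masks(bundle, config)
  steps <- c("index_mi_angio", criterion_order, "event_free_window")
  keep <- rep(TRUE, nrow(masks))
  flow <- data.table(criterion = "persons_in_registry", n_remaining = sum(keep))
  for (s in steps) {
    keep <- keep & masks[[s]]
    flow <- rbind(flow, data.table(criterion = s, n_remaining = sum(keep)))
  }
  out <- list(eligible = masks$person_id[keep], flowchart = flow)
  attr(out, "masks") <- masks
  out
}

#' Render the selection flowchart as a text tree
#'
#' @param flowchart the flowchart table from [apply_eligibility()].
#' @return character vector of lines, invisibly (also printed).
#' @export
format_flowchart <- function(flowchart) {
  lines <- sprintf("%s n = %d  %s",
                   c("", rep("  └─ ", nrow(flowchart) - 1L)),
                   flowchart$n_remaining, flowchart$criterion)
  cat(lines, sep = "\n")
  invisible(lines)
}
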