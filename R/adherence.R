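#' Adherence / artificial-censoring configuration
#'
#' Governs the pharmacoepidemiologic adherence algorithm: the assumed
#' daily dose per beta-blocker (100 mg metoprolol, 5 mg bisoprolol), the
#' maximum allowed refill gap (180 days; 90 in a sensitivity analysis),
#' and the condition codes whose occurrence overrides a deviation
#' (contraindications excuse stopping in the beta-blocker arm; new
#' indications excuse starting in the no-beta-blocker arm).
#'
#' @param daily_dose_mg named map drug -> assumed daily dose in mg.
#' @param gap_days maximum gap between the end of one dispensation's
#'   coverage and the next dispensation.
#' @param new_indication_codes,contraindication_codes symbolic code sets.
#' @param stockpiling if `TRUE` (default), early refills extend coverage
#'   from the end of the previous dispensation; if `FALSE`, each refill's
#'   coverage restarts at its dispense date.
#' @return object of class `adherence_config`.
#' @export
adherence_config <- function(
    daily_dose_mg = c(metoprolol = 100, bisoprolol = 5),
    gap_days = 180L,
    new_indication_codes = NEW_INDICATION_CODES,
    contraindication_codes = CONTRAINDICATION_CODES,
    stockpiling = TRUE) {
  if (gap_days < 1L)
    stop("configuration error: 'gap_days' must be >= 1", call. = FALSE)
  assert_positive(daily_dose_mg, "daily_dose_mg")
  cfg <- list(daily_dose_mg = daily_dose_mg,
              gap_days = as.integer(gap_days),
              new_indication_codes = new_indication_codes,
              contraindication_codes = contraindication_codes,
              stockpiling = isTRUE(stockpiling))
  class(cfg) <- "adherence_config"
  cfg
}

#' Dispensation coverage segments
#'
#' Each dispensation covers `floor(pill_count * pill_dose_mg / daily_dose)`
#' days.  Coverage starts at the dispense date or, when the previous
#' segment is still running (early refill), the day after it ends —
#' stockpiling extends coverage.  Adjacent or overlapping segments are
#' merged.
#'
#' @param dispensations beta-blocker dispensation rows (one or more
#'   persons); every `drug_class` must have a configured daily dose.
#' @param config an [adherence_config()].
#' @return data.table of segments: person_id, start_date, end_date
#'   (inclusive), dispensation_ids (list of input row numbers).
#' @export
dispensation_coverage <- function(dispensations,
                                  config = adherence_config()) {
  dd <- config$daily_dose_mg
  unknown <- setdiff(unique(dispensations$drug_class), names(dd))
  if (length(unknown))
    stop("configuration error: no daily dose configured for drug class ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!nrow(dispensations))
    return(data.table(person_id = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      dispensation_ids = list()))
  disp <- data.table(
    person_id = dispensations$person_id,
    d = as.integer(dispensations$dispense_date),
    dur = as.integer(floor(dispensations$pill_count *
                             dispensations$pill_dose_mg /
                             dd[dispensations$drug_class])),
    row = seq_len(nrow(dispensations))
  )
  if (any(dispensations$pill_count < 1L) || any(dispensations$pill_dose_mg <= 0))
    stop("invalid dispensation: pill_count must be >= 1 and pill_dose_mg > 0",
         call. = FALSE)
  setorder(disp, person_id, d)
  if (config$stockpiling) {
    # end_j = cumdur_j - 1 + max_{k<=j}(d_k - cumdur_{k-1}): running-max
    # closed form of "start at max(dispense date, previous end + 1)"
    disp[, cumdur := cumsum(dur), by = person_id]
    disp[, key := d - (cumdur - dur)]
    disp[, runmax := cummax(key), by = person_id]
    disp[, end := cumdur + runmax - 1L]
  } else {
    disp[, end := d + dur - 1L]
    disp[, end := cummax(end), by = person_id]
  }
  disp[, prev_end := shift(end), by = person_id]
  disp[, seg := cumsum(is.na(prev_end) | d > prev_end + 1L),
       by = person_id]
  segs <- disp[, .(start_day = d[1L], end_day = end[.N],
                   dispensation_ids = list(row)),
               by = .(person_id, seg)]
  segs[, `:=`(start_date = as.Date(start_day, origin = "1970-01-01"),
              end_date = as.Date(end_day, origin = "1970-01-01"))]
  segs[, c("seg", "start_day", "end_day") := NULL]
  setcolorder(segs, c("person_id", "start_date", "end_date",
                      "dispensation_ids"))
  segs[]
}

#' Per-protocol non-adherence / artificial-censoring dates
#'
#' Beta-blocker arm: the subject deviates at the first refill gap of
#' `gap_days` or more (including exhaustion of coverage); the censor date
#' is coverage end + `gap_days`, the first day the gap criterion is
#' violated.  A contraindication diagnosis on or before that coverage end
#' excuses the gap.  No-beta-blocker arm: the subject deviates at the
#' first beta-blocker dispensation after time zero, unless a new
#' indication diagnosis occurred on or before that dispensation date.
#'
#' @param subjects cohort from [assign_arm()].
#' @param bundle the `registry_bundle` (dispensations and diagnoses).
#' @param config an [adherence_config()].
#' @return data.table(person_id, censor_date) with `NA` for subjects who
#'   never deviate.
#' @export
nonadherence_date <- function(subjects, bundle,
                              config = adherence_config()) {
  gap <- config$gap_days
  ids <- subjects$person_id
  t0 <- setNames(as.integer(subjects$time_zero), ids)
  assign_day <- setNames(as.integer(subjects$assignment_date), ids)

  bb_ids <- subjects[arm == "beta_blocker", person_id]
  nb_ids <- subjects[arm == "no_beta_blocker", person_id]

  dsp <- bundle$dispensations[drug_class %in% BB_DRUGS &
                                person_id %in% ids,
                              .(person_id, drug_class, dispense_date,
                                pill_count, pill_dose_mg,
                                d = as.integer(dispense_date))]

  contra <- bundle$diagnoses[condition_code %in%
                               config$contraindication_codes &
                               person_id %in% bb_ids,
                             .(first_contra = min(as.integer(date), Inf)),
                             by = person_id]
  indic <- bundle$diagnoses[condition_code %in%
                              config$new_indication_codes &
                              person_id %in% nb_ids,
                            .(first_ind = min(as.integer(date), Inf)),
                            by = person_id]

  ## beta-blocker arm: gap rule over post-angiography coverage
  ang <- setNames(as.integer(subjects$angio_date), ids)
  bb_disp <- dsp[person_id %in% bb_ids]
  bb_disp <- bb_disp[d > ang[as.character(person_id)]]
  segs <- dispensation_coverage(bb_disp, config)
  segs[, `:=`(s = as.integer(start_date), e = as.integer(end_date))]
  setorder(segs, person_id, s)
  segs[, nxt := shift(s, -1L), by = person_id]
  segs <- merge(segs, contra, by = "person_id", all.x = TRUE)
  viol <- segs[(is.na(nxt) | nxt - e >= gap) &
                 !(!is.na(first_contra) & first_contra <= e)]
  bb_cens <- viol[, .(censor_day = min(e, Inf) + gap), by = person_id]
  # beta-blocker subjects with no post-angiography coverage at all:
  # exhausted from the assignment date onward
  uncovered <- setdiff(bb_ids, segs$person_id)
  if (length(uncovered)) {
    extra <- data.table(person_id = uncovered,
                        censor_day = assign_day[as.character(uncovered)] +
                          gap)
    cd <- contra[person_id %in% uncovered]
    excused <- cd[first_contra <= assign_day[as.character(person_id)],
                  person_id]
    extra <- extra[!person_id %in% excused]
    bb_cens <- rbind(bb_cens, extra)
  }

  ## no-beta-blocker arm: first beta-blocker dispensation after time zero
  nb_disp <- dsp[person_id %in% nb_ids]
  nb_disp <- nb_disp[d > t0[as.character(person_id)]]
  nb_first <- nb_disp[, .(first_bb = min(d, Inf)), by = person_id]
  nb_first <- merge(nb_first, indic, by = "person_id", all.x = TRUE)
  nb_cens <- nb_first[is.na(first_ind) | first_ind > first_bb,
                      .(person_id, censor_day = first_bb)]

  cens <- rbind(bb_cens, nb_cens)
  out <- data.table(person_id = ids)
  out <- merge(out, cens, by = "person_id", all.x = TRUE)
  out[, censor_date := as.Date(censor_day, origin = "1970-01-01")]
  out[, censor_day := NULL]
  setorder(out, person_id)
  out[]
}

#' Expand subjects into the discrete person-interval dataset
#'
#' Maps follow-up onto 1-based 30.4375-day intervals from time zero.
#' Follow-up ends at the earliest of the outcome event (which closes its
#' interval), the artificial censor date, the administrative end of data,
#' or the horizon; persons censored mid-interval contribute only complete
#' intervals (floor convention).  For the MI outcome under the
#' total-effect convention, death does not end follow-up: the person
#' contributes event-free intervals until administrative end or horizon.
#' Time-varying covariates: renal disease is carried forward from its
#' first diagnosis; the six co-medication classes indicate a dispensation
#' within the interval.
#'
#' @param subjects cohort from [assign_arm()].
#' @param bundle the `registry_bundle`.
#' @param censor_dates optional data.table(person_id, censor_date) from
#'   [nonadherence_date()]; `NULL` for intention-to-treat.
#' @param outcome_kind one of `"composite"`, `"death"`, `"mi"`.
#' @param total_effect for `outcome_kind = "mi"`, treat death as a
#'   non-event and keep following (total-effect convention).
#' @param horizon_months maximum number of intervals (60 = 5 years).
#' @param admin_end administrative end of data; defaults to the bundle's
#'   configured study end.
#' @return data.table of person-intervals with attributes
#'   `"censor_frame"` (at-risk rows for the censoring-weight models, with
#'   indicator `cens`), `"outcome_kind"`, `"dropped"` (persons with zero
#'   complete intervals).
#' @export
expand_person_time <- function(subjects, bundle, censor_dates = NULL,
                               outcome_kind = c("composite", "death", "mi"),
                               total_effect = TRUE, horizon_months = 60L,
                               admin_end = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  if (is.null(admin_end))
    admin_end <- bundle$meta$config$study_end %||%
      max(bundle$outcomes$date, subjects$time_zero)
  ad_day <- as.numeric(as.Date(admin_end)) - as.numeric(subjects$time_zero)

  t0 <- setNames(as.numeric(subjects$time_zero), subjects$person_id)
  oc <- bundle$outcomes[person_id %in% subjects$person_id]
  oc <- oc[, .(person_id, event, d = as.numeric(date) -
                 t0[as.character(person_id)])]
  if (nrow(oc[d <= 0]))
    stop("alignment error: outcome dated at/before time zero for person(s) ",
         paste(head(oc[d <= 0, unique(person_id)], 5L), collapse = ", "),
         " (should have been excluded upstream)", call. = FALSE)
  firsts <- oc[, .(d_death = min(d[event == "death"], Inf),
                   d_mi = min(d[event == "mi"], Inf)), by = person_id]
  s <- merge(subjects[, .(person_id, arm)], firsts, by = "person_id",
             all.x = TRUE)
  s[is.na(d_death), d_death := Inf]
  s[is.na(d_mi), d_mi := Inf]
  setorder(s, person_id)
  ord <- match(s$person_id, subjects$person_id)
  ad <- ad_day[ord]

  cn <- rep(Inf, nrow(s))
  if (!is.null(censor_dates)) {
    cd <- merge(s[, .(person_id)], censor_dates, by = "person_id",
                all.x = TRUE)
    setorder(cd, person_id)
    cn <- as.numeric(cd$censor_date) - t0[as.character(s$person_id)]
    cn[is.na(cn)] <- Inf
    cn[cn < 0] <- 0
  }

  ev <- switch(outcome_kind,
               composite = pmin(s$d_death, s$d_mi),
               death = s$d_death,
               mi = s$d_mi)
  if (outcome_kind == "mi") {
    if (total_effect) {
      cn <- ifelse(s$d_death <= cn, Inf, cn)  # no deviation after death
    } else {
      cn <- pmin(cn, s$d_death)               # death censors
    }
  }

  H <- as.integer(horizon_months)
  t_ev <- interval_of(ev)
  event_happens <- is.finite(ev) & ev <= cn & ev <= ad & t_ev <= H
  n_int <- ifelse(event_happens, t_ev,
                  pmin(complete_intervals(cn), complete_intervals(ad), H))
  art <- !event_happens & is.finite(cn) & cn <= ad &
    complete_intervals(cn) <= H
  # censoring event interval (for the censoring-weight risk sets)
  tc <- ifelse(art, complete_intervals(pmin(cn, 1e9)) + 1L, NA_integer_)
  tc_ok <- art & !is.na(tc) & tc <= pmin(complete_intervals(ad), H)

  n_ext <- n_int + as.integer(tc_ok)  # censored persons get the event row
  keep <- n_ext > 0L
  dropped <- s$person_id[!keep]

  idx <- rep(which(keep), n_ext[keep])
  frame <- data.table(
    person_id = s$person_id[idx],
    arm = s$arm[idx],
    t = sequence(n_ext[keep])
  )
  frame[, cens := as.integer(tc_ok[idx] & t == n_ext[idx])]
  mark <- function(dvec) {
    ti <- interval_of(dvec)[idx]
    as.integer(is.finite(dvec[idx]) & frame$t == ti & frame$cens == 0L &
                 ti <= n_int[idx])
  }
  frame[, event_death := mark(s$d_death)]
  frame[, event_mi := mark(s$d_mi)]
  frame[, event_composite := mark(pmin(s$d_death, s$d_mi))]
  frame[, event := switch(outcome_kind, composite = event_composite,
                          death = event_death, mi = event_mi)]
  frame[, adherent := as.integer(t <= complete_intervals(cn[idx]))]
  # flag the last retained interval of persons whose follow-up the
  # artificial censoring curtailed
  frame[, artificially_censored := as.integer(tc_ok[idx] & t == n_int[idx])]

  ## time-varying covariates
  renal_dx <- bundle$diagnoses[condition_code == "renal_disease" &
                                 person_id %in% s$person_id,
                               .(rd = min(as.numeric(date), Inf)),
                               by = person_id]
  frame[, renal := 0L]
  if (nrow(renal_dx)) {
    renal_dx[, onset := pmax(interval_of(pmax(rd -
               t0[as.character(person_id)], 0)), 1L)]
    frame[renal_dx, on = "person_id",
          renal := as.integer(t >= i.onset)]
  }
  comed <- bundle$dispensations[drug_class %in% COMED_CLASSES &
                                  person_id %in% s$person_id,
                                .(person_id, drug_class,
                                  dd = as.numeric(dispense_date) -
                                    t0[as.character(person_id)])]
  comed <- comed[dd > 0]
  comed[, t := interval_of(dd)]
  comed <- unique(comed[, .(person_id, drug_class, t)])
  for (cls in COMED_CLASSES) {
    frame[, (cls) := 0L]
    hit <- comed[drug_class == cls]
    if (nrow(hit))
      frame[hit, on = c("person_id", "t"), (cls) := 1L]
  }

  censor_frame <- NULL
  if (!is.null(censor_dates)) censor_frame <- copy(frame)
  frame <- frame[cens == 0L]
  frame[, cens := NULL]

  setattr(frame, "outcome_kind", outcome_kind)
  setattr(frame, "total_effect", total_effect)
  setattr(frame, "horizon", H)
  setattr(frame, "dropped", dropped)
  setattr(frame, "censor_frame", censor_frame)
  frame[]
}
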