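#' Covariate balance: standardized mean differences before/after weighting
#'
#' Binary covariates and categorical levels use
#' `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0)) / 2)`; continuous covariates
#' use `|m1 - m0| / sqrt((v1 + v0) / 2)`.  Weighted columns use weighted
#' proportions, means and (population-style) variances.  Missing
#' percentages come from the cohort's pre-imputation `miss_*` flags.
#'
#' @param subjects imputed cohort from [impute_baseline()].
#' @param weights per-person weights: a numeric vector aligned with
#'   `subjects`, a `weight_set`, or `NULL` (unweighted only).
#' @param covariates covariate names; default all in `"covinfo"`.
#' @return data.table: covariate, level, treated/control summaries,
#'   missing %, `smd`, `smd_weighted`.
#' @export
balance_table <- function(subjects, weights = NULL, covariates = NULL) {
  info <- attr(subjects, "covinfo")
  covariates <- covariates %||% info$names
  if (inherits(weights, "weight_set"))
    weights <- weights$baseline[match(subjects$person_id, person_id), sw]
  w <- weights %||% rep(1, nrow(subjects))
  if (any(!is.finite(w) | w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  a <- subjects$arm == "beta_blocker"

  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) {
    m <- wmean(x, w)
    sum(w * (x - m)^2) / sum(w)
  }
  smd_bin <- function(p1, p0) {
    den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    ifelse(den == 0, ifelse(p1 == p0, 0, Inf), abs(p1 - p0) / den)
  }
  smd_cont <- function(m1, m0, v1, v0) {
    den <- sqrt((v1 + v0) / 2)
    ifelse(den == 0, ifelse(m1 == m0, 0, Inf), abs(m1 - m0) / den)
  }

  rows <- list()
  for (nm in covariates) {
    v <- subjects[[nm]]
    miss_col <- paste0("miss_", nm)
    mpct <- if (miss_col %in% names(subjects))
      100 * mean(subjects[[miss_col]]) else 100 * mean(is.na(v))
    if (is.numeric(v) && length(unique(v[!is.na(v)])) > 2L) {
      m1u <- mean(v[a]); m0u <- mean(v[!a])
      rows[[length(rows) + 1L]] <- data.table(
        covariate = nm, level = "",
        treated = m1u, control = m0u, missing_pct = mpct,
        smd = smd_cont(m1u, m0u, var(v[a]) * (sum(a) - 1) / sum(a),
                       var(v[!a]) * (sum(!a) - 1) / sum(!a)),
        smd_weighted = smd_cont(wmean(v[a], w[a]), wmean(v[!a], w[!a]),
                                wvar(v[a], w[a]), wvar(v[!a], w[!a])))
    } else {
      levs <- if (is.numeric(v)) 1 else setdiff(sort(unique(v)), NA)
      for (lv in levs) {
        x <- as.numeric(v == lv)
        p1u <- mean(x[a]); p0u <- mean(x[!a])
        rows[[length(rows) + 1L]] <- data.table(
          covariate = nm,
          level = if (is.numeric(v)) "" else as.character(lv),
          treated = p1u, control = p0u, missing_pct = mpct,
          smd = smd_bin(p1u, p0u),
          smd_weighted = smd_bin(wmean(x[a], w[a]), wmean(x[!a], w[!a])))
      }
    }
  }
  rbindlist(rows)
}
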