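# Interval grid: discrete-time "months" of 30.4375 days, 1-based indices.
MONTH_DAYS <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map days since time zero to a 1-based month interval
#'
#' Interval `t` covers days `[(t-1) * 30.4375, t * 30.4375)`; an event on
#' day `d >= 0` therefore falls in interval `floor(d / 30.4375) + 1`.
#'
#' @param days numeric vector of days since time zero (>= 0); non-finite
#'   values yield `NA`.
#' @return integer vector of interval indices.
#' @export
interval_of <- function(days) {
  out <- rep(NA_integer_, length(days))
  ok <- is.finite(days)
  out[ok] <- as.integer(floor(days[ok] / MONTH_DAYS)) + 1L
  out
}

# Number of *complete* intervals contained in `days` of follow-up
# (floor convention for censoring; events instead close their interval).
# +Inf maps to the largest representable count so pmin() picks the bound.
complete_intervals <- function(days) {
  out <- rep(.Machine$integer.max, length(days))
  ok <- is.finite(days)
  out[ok] <- pmax(as.integer(floor(days[ok] / MONTH_DAYS)), 0L)
  out[!ok & days < 0] <- 0L
  out
}

# Mid-interval day offset used when the generator materializes a discrete
# interval index as a calendar date; round-trips through interval_of().
interval_mid_day <- function(t) as.integer(floor((t - 0.5) * MONTH_DAYS))

first_true_col <- function(m) {
  # index of first TRUE per row, NA_integer_ when none
  hit <- rowSums(m) > 0L
  idx <- max.col(m, ties.method = "first")
  ifelse(hit, idx, NA_integer_)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop("configuration error: '", what, "' must be a probability in [0, 1]",
         call. = FALSE)
  invisible(x)
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0))
    stop("configuration error: '", what, "' must be positive", call. = FALSE)
  invisible(x)
}

config_hash <- function(x) rlang::hash(x)

# Derive independent substream seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n, labels = NULL) {
  s <- withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
  if (!is.null(labels)) names(s) <- labels
  s
}
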