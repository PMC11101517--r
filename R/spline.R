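#' Restricted cubic spline specification for the time trend
#'
#' Knots default to 6, 12, 24 and 48 months of follow-up.
#'
#' @param knots strictly increasing knot positions in months (>= 3).
#' @return object of class `spline_spec`.
#' @export
spline_spec <- function(knots = c(6, 12, 24, 48)) {
  if (length(knots) < 3L)
    stop("configuration error: restricted cubic spline needs >= 3 knots",
         call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("configuration error: knots must be strictly increasing",
         call. = FALSE)
  structure(list(knots = as.numeric(knots)), class = "spline_spec")
}

#' Restricted (natural) cubic spline basis
#'
#' Standard restricted cubic spline construction: with knots
#' `k_1 < ... < k_K`, the basis is linear below `k_1` and above `k_K`,
#' and the j-th nonlinear term is
#' \deqn{b_j(t) = \big[(t-k_j)_+^3 - (t-k_{K-1})_+^3 (k_K-k_j)/(k_K-k_{K-1})
#'   + (t-k_K)_+^3 (k_{K-1}-k_j)/(k_K-k_{K-1})\big] / (k_K-k_1)^2}
#' for `j = 1, ..., K-2`.
#'
#' @param t months of follow-up (vector, >= 0).
#' @param spec a [spline_spec()].
#' @return matrix with columns `t, rcs1, ..., rcs(K-2)`.
#' @export
rcs_basis <- function(t, spec = spline_spec()) {
  k <- spec$knots
  K <- length(k)
  pos3 <- function(x) pmax(x, 0)^3
  scale <- (k[K] - k[1])^2
  B <- matrix(0, length(t), K - 1L)
  B[, 1L] <- t
  for (j in seq_len(K - 2L)) {
    B[, j + 1L] <- (pos3(t - k[j]) -
                      pos3(t - k[K - 1L]) * (k[K] - k[j]) / (k[K] - k[K - 1L]) +
                      pos3(t - k[K]) * (k[K - 1L] - k[j]) / (k[K] - k[K - 1L])) /
      scale
  }
  colnames(B) <- c("t", paste0("rcs", seq_len(K - 2L)))
  B
}

# append rcs columns (rcs1..) for the existing `t` column; returns the
# data.table with attribute "rcs_cols" naming the time-basis columns
add_rcs_columns <- function(dt, spec = spline_spec()) {
  B <- rcs_basis(dt$t, spec)
  for (j in 2:ncol(B)) set(dt, j = colnames(B)[j], value = B[, j])
  setattr(dt, "rcs_cols", colnames(B))
  dt
}
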