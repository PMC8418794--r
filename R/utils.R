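#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats approx coef dnbinom dpois integrate model.matrix optim
#'   plogis pnorm predict qlogis quantile rbinom rgamma rnbinom rnorm rpois
#'   runif sd setNames var vcov glm binomial poisson quasipoisson as.formula
#'   terms delete.response reformulate
#' @importFrom utils head modifyList
NULL

# consistent error classes so callers can condition on failure modes
stop_mdsm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mdsm_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Pearson chi-squared statistic for observed vs expected counts
#'
#' Aggregated goodness-of-fit statistic
#' \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / E_g} used to compare observed group
#' totals with model-expected totals (for example, birds recorded swimming vs
#' flying against the per-platform sums of fitted segment means).
#'
#' @param observed Numeric vector of observed totals per group.
#' @param expected Numeric vector of expected totals per group (same length,
#'   all positive).
#' @return A single number, the Pearson chi-squared statistic.
#' @examples
#' pearson_chisq(c(501, 533), c(405, 632))
#' @export
pearson_chisq <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop_mdsm("`observed` and `expected` must have the same length.",
              "mdsm_validation_error")
  }
  if (any(expected <= 0)) {
    stop_mdsm("All expected counts must be positive.", "mdsm_validation_error")
  }
  sum((observed - expected)^2 / expected)
}

# block-diagonal assembly of a list of square matrices; 0x0 when empty
block_diag <- function(mats) {
  mats <- mats[vapply(mats, function(m) nrow(m) > 0L, logical(1))]
  if (length(mats) == 0L) return(matrix(0, 0, 0))
  dims <- vapply(mats, nrow, integer(1))
  total <- sum(dims)
  out <- matrix(0, total, total)
  at <- 0L
  nms <- character(0)
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- m
    nms <- c(nms, colnames(m) %||% rep("", nrow(m)))
    at <- at + nrow(m)
  }
  dimnames(out) <- list(nms, nms)
  out
}

# symmetric pseudo-inverse with PSD check; warns via `context` label
psd_inverse <- function(V, context = "covariance") {
  if (nrow(V) == 0L) return(V)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop_mdsm(sprintf("%s matrix is not positive semi-definite.", context),
              "mdsm_numeric_error")
  }
  if (min(ev) < 1e-10 * max(ev, 1)) {
    rlang::warn(sprintf("%s matrix is singular; using a pseudo-inverse.", context))
    return(MASS::ginv(V))
  }
  solve(V)
}
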