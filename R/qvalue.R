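# Storey q-values with spline-smoothed pi0 estimation.

#' Estimate the null proportion pi0
#'
#' Storey-Tibshirani estimator: for each lambda on the grid,
#' `pi0(lambda) = #{p > lambda} / (m * (1 - lambda))`; a cubic smoothing
#' spline (3 df) over the grid is evaluated at the largest lambda and the
#' result clipped to (0, 1].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param lambda Grid of lambda values (default 0, 0.05, ..., 0.90).
#' @return The pi0 estimate (scalar in (0, 1]).
#' @export
estimate_pi0 <- function(p_values, lambda = seq(0, 0.90, by = 0.05)) {
  check_pvalues(p_values)
  m <- length(p_values)
  pi0_lambda <- vapply(lambda,
                       function(l) sum(p_values > l) / (m * (1 - l)),
                       numeric(1L))
  fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values
#'
#' Converts p-values to q-values (per-gene FDR analogues):
#' `q(i) = min over j with p(j) >= p(i) of pi0 * m * p(j) / rank(j)`,
#' with pi0 from [estimate_pi0()]. The mapping is monotone non-decreasing in
#' p and invariant under permutation of the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\], length >= 2.
#' @param pi0 Optional fixed pi0 (skips estimation).
#' @return Numeric vector of q-values, same order as the input; the pi0 used
#'   is attached as attribute `pi0`.
#' @export
qvalues <- function(p_values, pi0 = NULL) {
  check_pvalues(p_values)
  if (length(p_values) < 2L) {
    stop("need at least 2 p-values", call. = FALSE)
  }
  if (is.null(pi0)) pi0 <- estimate_pi0(p_values)
  stopifnot(pi0 > 0, pi0 <= 1)
  m <- length(p_values)
  o <- order(p_values)
  raw <- pi0 * m * p_values[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
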