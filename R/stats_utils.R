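# Small statistical utilities: SE back-calculation and 95% confidence
# intervals for reported estimates.

#' Back-calculate a standard error from an estimate and its p-value
#'
#' Given a point estimate and its two-sided p-value under a Wald test, the
#' implied standard error is `|estimate| / z` with `z` the upper `1 - p/2`
#' standard normal quantile. Useful when a method reports an estimate and
#' p-value but no interval. As `p` approaches 1 the quantile approaches 0 and
#' the result overflows to `Inf`.
#'
#' @param estimate Nonzero point estimate (vectorized).
#' @param p Two-sided p-value in (0, 1).
#' @return Standard error(s).
#' @examples
#' se_from_estimate_and_p(0.16, 7.5e-4)  # ~0.0504
#' @export
se_from_estimate_and_p <- function(estimate, p) {
  if (any(p <= 0 | p >= 1)) {
    abort("p must lie strictly inside (0, 1)", class = "pleioscan_domain_error")
  }
  if (any(estimate == 0)) {
    abort("estimate must be nonzero", class = "pleioscan_domain_error")
  }
  abs(estimate) / qnorm(1 - p / 2)
}

#' 95% confidence interval from an estimate and standard error
#'
#' `estimate` plus/minus `z * se`, with `z = 1.96` by convention (matching how
#' intervals are typically printed; the exact quantile can be supplied
#' instead).
#'
#' @param estimate Point estimate (vectorized).
#' @param se Standard error (`se >= 0`).
#' @param z Normal quantile, default 1.96.
#' @return Tibble with `estimate`, `se`, `ci_low`, `ci_high`.
#' @examples
#' ci95(0.14, 0.0475)
#' @export
ci95 <- function(estimate, se, z = 1.96) {
  if (any(se < 0)) abort("se must be non-negative",
                         class = "pleioscan_domain_error")
  tibble::tibble(estimate = estimate, se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se)
}
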