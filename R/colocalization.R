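# Single-causal-variant Bayesian colocalization from approximate Bayes
# factors.
#
# At a locus of n harmonized variants, five hypotheses are compared:
#   H0 neither trait has a causal variant;
#   H1/H2 only trait 1 / only trait 2 has one;
#   H3 both do, at two distinct variants;
#   H4 both do, at the same variant.
# Per-variant evidence enters as Wakefield approximate Bayes factors computed
# from (beta, se) and a prior effect-scale; hypothesis weights are assembled
# entirely in log space.

#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximation: with \eqn{V = se^2}, \eqn{W} the prior effect
#' variance, \eqn{z = \beta/se} and shrinkage \eqn{r = W/(V+W)},
#' \deqn{\log ABF = \tfrac12 \log(1 - r) + \tfrac12 z^2 r.}
#' Positive values favour association over the null.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`; vectorized).
#' @param prior_sd Prior standard deviation of the true effect on the same
#'   scale as `beta`. Default 0.2, the conventional prior for log odds ratios
#'   of a case-control trait.
#' @return Numeric vector of log ABFs (natural log).
#' @examples
#' log_abf(0.6, 0.1, prior_sd = 0.2)  # ~13.595
#' @export
log_abf <- function(beta, se, prior_sd = 0.2) {
  if (any(se <= 0)) abort("se must be positive", class = "pleioscan_domain_error")
  if (any(prior_sd <= 0)) {
    abort("prior_sd must be positive", class = "pleioscan_domain_error")
  }
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + 0.5 * (beta / se)^2 * r
}

#' Colocalization priors
#'
#' Per-variant prior probabilities: `p1` causal for trait 1 only, `p2` for
#' trait 2 only, `p12` for both. Defaults are the conventional
#' \eqn{10^{-4}, 10^{-4}, 10^{-5}}.
#'
#' @param p1,p2,p12 Prior probabilities; `p1`, `p2` must be positive and
#'   `p12` non-negative, with `p1 + p2 + p12` small enough that `n` times it
#'   stays below 1 for any analyzed locus.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (p1 <= 0 || p2 <= 0 || p12 < 0 || p1 + p2 + p12 >= 1) {
    abort("priors must satisfy p1, p2 > 0, p12 >= 0, p1 + p2 + p12 < 1",
          class = "pleioscan_domain_error")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# log(exp(a) - exp(b)) for a >= b, without leaving log space.
.log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

.log_sum_exp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Combines two traits' per-variant log ABFs over a locus into posterior
#' probabilities PP_H0..PP_H4. Writing \eqn{S_1, S_2} for the log-sum-exp of
#' each trait's log ABFs and \eqn{S_{12}} for that of their elementwise sum,
#' the unnormalized log weights are 0, \eqn{\log p_1 + S_1},
#' \eqn{\log p_2 + S_2}, \eqn{\log p_1 p_2 + \log(e^{S_1 + S_2} - e^{S_{12}})}
#' (computed stably; exactly \eqn{-\infty} at n = 1, where no distinct-variant
#' configuration exists), and \eqn{\log p_{12} + S_{12}}.
#'
#' @param labf1,labf2 Equal-length numeric vectors of log ABFs.
#' @param priors A [coloc_priors()] object.
#' @return One-row tibble: `n`, `pp_h0`..`pp_h4`, `pp_shared` (= `pp_h4`),
#'   `pp_distinct` (= `pp_h3`).
#' @examples
#' coloc_posteriors(c(0, 0, 13.6, 0, 0), c(0, 0, 13.6, 0, 0))
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors()) {
  n <- length(labf1)
  if (n < 1 || length(labf2) != n) {
    abort("labf1 and labf2 must be equal-length vectors with n >= 1",
          class = "pleioscan_domain_error")
  }
  s1 <- .log_sum_exp(labf1)
  s2 <- .log_sum_exp(labf2)
  s12 <- .log_sum_exp(labf1 + labf2)
  lw <- c(
    h0 = 0,
    h1 = log(priors$p1) + s1,
    h2 = log(priors$p2) + s2,
    h3 = log(priors$p1) + log(priors$p2) + .log_diff_exp(s1 + s2, s12),
    h4 = if (priors$p12 > 0) log(priors$p12) + s12 else -Inf)
  pp <- exp(lw - .log_sum_exp(lw))
  tibble::tibble(
    n = n,
    pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
    pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
    pp_shared = pp[["h4"]], pp_distinct = pp[["h3"]])
}

#' Colocalize one locus from harmonized summary statistics
#'
#' Computes per-trait log ABFs with [log_abf()] over the locus's harmonized
#' variants and feeds them to [coloc_posteriors()]. Variants lacking a finite
#' (beta, se) with `se > 0` in either trait are dropped first; the dropped
#' count is in the `n_dropped` column.
#'
#' @param locus Data frame with columns `beta_a`, `se_a`, `beta_b`, `se_b`
#'   (e.g. a [harmonized_pair] subset to one LD block).
#' @param priors A [coloc_priors()] object.
#' @param prior_sd Length-2 (or recycled) vector of prior effect scales for
#'   the two traits; default 0.2 each.
#' @return One-row tibble as [coloc_posteriors()], plus `n_dropped`.
#' @export
colocalize_locus <- function(locus, priors = coloc_priors(),
                             prior_sd = c(0.2, 0.2)) {
  prior_sd <- rep_len(prior_sd, 2)
  ok <- is.finite(locus$beta_a) & is.finite(locus$se_a) & locus$se_a > 0 &
    is.finite(locus$beta_b) & is.finite(locus$se_b) & locus$se_b > 0
  n_dropped <- sum(!ok)
  locus <- locus[ok, , drop = FALSE]
  if (nrow(locus) == 0) {
    abort("no usable variants at this locus", class = "pleioscan_domain_error")
  }
  out <- coloc_posteriors(
    log_abf(locus$beta_a, locus$se_a, prior_sd[1]),
    log_abf(locus$beta_b, locus$se_b, prior_sd[2]),
    priors)
  out$n_dropped <- n_dropped
  out
}
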