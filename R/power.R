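# Analytical power for two-sample MR with a binary outcome (the mRnd-style
# non-centrality approximation).

#' Power of a two-sample MR test with a binary outcome
#'
#' Closed-form approximation based on the non-centrality parameter
#' `lambda = n * r2 * k * (1 - k) * log(OR)^2`:
#' `power = Phi(sqrt(lambda) - z) + Phi(-sqrt(lambda) - z)` with
#' `z = qnorm(1 - alpha/2)`.  At OR = 1 the power equals alpha exactly, and
#' the formula is symmetric in OR vs 1/OR.
#'
#' @param n outcome-GWAS sample size.
#' @param r2 proportion of exposure variance explained by the instrument,
#'   in (0,1).
#' @param k proportion of cases among `n`, in (0,1).
#' @param odds_ratio assumed causal OR per SD of exposure (> 0).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @return Power in (0,1).  Vectorized over all arguments.
#' @export
mr_power_binary <- function(n, r2, k, odds_ratio, alpha = 0.05) {
  stopifnot(all(n > 0), all(r2 > 0 & r2 < 1), all(k > 0 & k < 1),
            all(odds_ratio > 0), all(alpha > 0 & alpha < 1))
  lambda <- n * r2 * k * (1 - k) * log(odds_ratio)^2
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(lambda) - z) + stats::pnorm(-sqrt(lambda) - z)
}
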