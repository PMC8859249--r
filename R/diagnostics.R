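# Heterogeneity and pleiotropy diagnostics: Cochran's Q, the Egger
# intercept test, MR-PRESSO (global / per-SNP outlier / distortion),
# leave-one-out series, and funnel-plot data.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (ratio_j - theta)^2)` with the upper-tail chi-square
#' p-value on J - 1 degrees of freedom.
#'
#' @param r a `ratio_set` from [wald_ratios()].
#' @param theta the causal effect at which to evaluate Q (usually the
#'   fixed-effect IVW estimate).
#' @return List with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(r, theta) {
  if (nrow(r) < 2) stop("Cochran's Q requires at least 2 SNPs", call. = FALSE)
  q <- sum(r$weight * (r$ratio - theta)^2)
  df <- nrow(r) - 1
  list(Q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept component of [mr_egger()] with its z-test; a
#' non-zero intercept indicates directional pleiotropy.
#'
#' @param h a harmonized set with at least 3 SNPs.
#' @return List with `intercept`, `se`, `ci_low`, `ci_high`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  ic <- mr_egger(h, binary = FALSE)$intercept
  list(intercept = ic$beta, se = ic$se, ci_low = ic$ci_low,
       ci_high = ic$ci_high, pval = ic$pval)
}

# leave-one-out fixed-effect IVW estimates, vectorized over the left-out SNP
loo_ivw_theta <- function(ratio, weight) {
  sw <- sum(weight); swb <- sum(weight * ratio)
  (swb - weight * ratio) / (sw - weight)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based pleiotropy test.  (1) Global: the observed residual sum
#' of squares `RSS = sum_j (beta_out_j - theta_(-j) beta_exp_j)^2 /
#' se_out_j^2` (theta_(-j) the leave-one-out fixed-effect IVW estimate) is
#' compared against `n_sim` parametric simulations drawing `beta_exp* ~
#' N(beta_exp, se_exp^2)` and `beta_out* ~ N(theta_(-j) beta_exp,
#' se_out^2)`.  (2) Outlier: each SNP's observed residual against its
#' simulated distribution, Bonferroni-adjusted across J.  (3) Corrected
#' estimate: fixed-effect IVW after removing flagged outliers.
#' (4) Distortion: the raw-vs-corrected difference against a null from
#' removing random subsets of the same size.  Empirical p-values carry a
#' +1/(n_sim+1) continuity correction so they are never zero.
#'
#' @param h a harmonized set with at least 4 SNPs.
#' @param n_sim number of parametric simulations (default 1000).
#' @param seed RNG seed (reproducible when supplied).
#' @param outlier_sig significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param binary outcome is binary (OR scale on the corrected estimate).
#' @return List with `global_pval`, `outliers` (data frame of flagged SNPs
#'   with adjusted p-values), `outlier_pvals` (all SNPs), `raw`,
#'   `corrected` ([mr_estimate()]s) and `distortion_pval` (`NA` when no
#'   outliers are flagged).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_sig = 0.05,
                      binary = TRUE) {
  k <- harmonized_kept(h)
  j <- nrow(k)
  if (j < 4) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  ratio <- k$beta_out / k$beta_exp
  weight <- (k$beta_exp / k$se_out)^2
  th_loo <- loo_ivw_theta(ratio, weight)
  # outcome-scale residuals; identical to weight_j (ratio_j - th_loo_j)^2
  res_obs <- (k$beta_out - th_loo * k$beta_exp)^2 / k$se_out^2
  rss_obs <- sum(res_obs)

  # parametric null: J x n_sim draws
  bx <- matrix(stats::rnorm(j * n_sim, k$beta_exp, k$se_exp), nrow = j)
  by <- matrix(stats::rnorm(j * n_sim, th_loo * k$beta_exp, k$se_out), nrow = j)
  rs <- by / bx
  ws <- (bx / k$se_out)^2
  sw <- colSums(ws); swb <- colSums(ws * rs)
  th_loo_sim <- sweep(-(ws * rs), 2, swb, `+`) / sweep(-ws, 2, sw, `+`)
  res_sim <- (by - th_loo_sim * bx)^2 / k$se_out^2
  rss_sim <- colSums(res_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_out_raw <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
  p_out_adj <- pmin(1, p_out_raw * j)
  flagged <- which(p_out_adj < outlier_sig)

  raw <- mr_ivw(h, "fixed", binary = binary)
  raw$method <- "IVW (raw)"
  if (length(flagged) == j) stop("no stable subset: all SNPs flagged as outliers",
                                 call. = FALSE)
  if (length(flagged) > 0) {
    keep <- setdiff(seq_len(j), flagged)
    core <- ivw_fixed_core(ratio[keep], weight[keep])
    corrected <- mr_estimate("MR-PRESSO (outlier-corrected)",
                             unname(core["theta"]), unname(core["se"]),
                             length(keep), binary = binary)
    # distortion null: remove random subsets of the same size
    d_obs <- corrected$beta - raw$beta
    d_null <- vapply(seq_len(n_sim), function(b) {
      drop_b <- sample.int(j, length(flagged))
      core_b <- ivw_fixed_core(ratio[-drop_b], weight[-drop_b])
      unname(core_b["theta"]) - raw$beta
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  } else {
    corrected <- raw
    corrected$method <- "MR-PRESSO (no outliers)"
    distortion_pval <- NA_real_
  }

  list(global_pval = global_pval,
       outliers = data.frame(snp_id = k$snp_id[flagged],
                             pval_adj = p_out_adj[flagged],
                             stringsAsFactors = FALSE),
       outlier_pvals = data.frame(snp_id = k$snp_id, pval_raw = p_out_raw,
                                  pval_adj = p_out_adj,
                                  stringsAsFactors = FALSE),
       raw = raw, corrected = corrected, distortion_pval = distortion_pval)
}

#' Leave-one-out analysis
#'
#' Fixed-effect IVW re-estimated J times, each run omitting one SNP, in the
#' input order.  A stable association shows no single-SNP removal that
#' drastically changes the estimate.
#'
#' @param h a harmonized set with at least 3 SNPs.
#' @param binary outcome is binary (OR scale).
#' @return Data frame: `snp_left_out`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `or`, `or_ci_low`, `or_ci_high`.
#' @export
leave_one_out <- function(h, binary = TRUE) {
  k <- harmonized_kept(h)
  j <- nrow(k)
  if (j < 3) stop("leave-one-out requires at least 3 SNPs", call. = FALSE)
  ratio <- k$beta_out / k$beta_exp
  weight <- (k$beta_exp / k$se_out)^2
  ests <- lapply(seq_len(j), function(i) {
    core <- ivw_fixed_core(ratio[-i], weight[-i])
    e <- mr_estimate("IVW (fixed)", unname(core["theta"]), unname(core["se"]),
                     j - 1, binary = binary)
    e
  })
  out <- estimates_frame(ests)
  out$method <- NULL
  cbind(data.frame(snp_left_out = k$snp_id, stringsAsFactors = FALSE), out)
}

#' Funnel-plot data
#'
#' Per-SNP (ratio, precision = 1/ratio_se) pairs with the IVW reference
#' value attached; symmetric scatter around the reference line suggests
#' balanced pleiotropy.  `symmetry_test = TRUE` adds an exploratory t-test
#' comparing the mean ratio of the higher-precision half against the
#' lower-precision half (not a formal pleiotropy test).
#'
#' @param r a `ratio_set` from [wald_ratios()].
#' @param symmetry_test run the exploratory precision-split t-test.
#' @return Data frame `snp_id`, `ratio`, `precision`, with attributes
#'   `ivw_theta` and (optionally) `symmetry_pval`.
#' @export
funnel_data <- function(r, symmetry_test = FALSE) {
  out <- data.frame(snp_id = r$snp_id, ratio = r$ratio,
                    precision = 1 / r$ratio_se, stringsAsFactors = FALSE)
  attr(out, "ivw_theta") <- if (nrow(r) >= 1)
    unname(ivw_fixed_core(r$ratio, r$weight)["theta"]) else NA_real_
  if (symmetry_test && nrow(r) >= 4) {
    hi <- out$precision >= stats::median(out$precision)
    attr(out, "symmetry_pval") <-
      stats::t.test(out$ratio[hi], out$ratio[!hi])$p.value
  }
  out
}

#' Assemble the full pleiotropy report
#'
#' Bundles Cochran's Q (at the fixed-effect IVW estimate), the Egger
#' intercept test, MR-PRESSO, the leave-one-out series and the funnel data
#' into one report structure.
#'
#' @param h a harmonized set.
#' @param n_sim,seed MR-PRESSO simulation controls.
#' @param binary outcome is binary.
#' @return A `pleiotropy_report` list.
#' @export
pleiotropy_report <- function(h, n_sim = 1000, seed = NULL, binary = TRUE) {
  r <- wald_ratios(h)
  theta <- unname(ivw_fixed_core(r$ratio, r$weight)["theta"])
  q <- cochran_q(r, theta)
  presso <- mr_presso(h, n_sim = n_sim, seed = seed, binary = binary)
  rep <- list(q_stat = q$Q, q_df = q$df, q_pval = q$pval,
              egger_intercept = egger_intercept_test(h),
              presso_global_pval = presso$global_pval,
              presso_outliers = presso$outliers,
              presso_distortion_pval = presso$distortion_pval,
              presso_corrected = presso$corrected,
              loo_series = leave_one_out(h, binary = binary),
              funnel_points = funnel_data(r))
  class(rep) <- "pleiotropy_report"
  rep
}
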