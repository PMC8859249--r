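# Causal-effect estimators on a harmonized set: Wald ratios, IVW
# (fixed / multiplicative-random, penalized, robust), MR-Egger, simple and
# weighted medians with parametric-bootstrap SEs, and profile maximum
# likelihood.  Conventions: two-sided normal p-values throughout; the
# multiplicative random-effects scale factor is floored at 1.

Z95 <- stats::qnorm(0.975)

#' Construct an MR estimate record
#'
#' @param method method label.
#' @param beta,se causal effect (log-OR per SD for a binary outcome) and SE.
#' @param n_snps number of SNPs used.
#' @param binary whether the outcome is binary (enables the OR scale).
#' @return An `mr_estimate` list with `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `n_snps` and, when `binary`, `or`, `or_ci_low`, `or_ci_high`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, binary = FALSE) {
  ci_low <- beta - Z95 * se
  ci_high <- beta + Z95 * se
  out <- list(method = method, beta = beta, se = se,
              ci_low = ci_low, ci_high = ci_high,
              pval = 2 * stats::pnorm(-abs(beta / se)),
              n_snps = as.integer(n_snps))
  class(out) <- "mr_estimate"
  if (binary) out <- to_odds_ratio(out)
  out
}

#' Express an estimate on the odds-ratio scale
#'
#' Exponentiates the effect and its normal-approximation 95% CI
#' (`beta +/- 1.96 se`), attaching `or`, `or_ci_low`, `or_ci_high`.
#'
#' @param est an `mr_estimate` for a binary outcome.
#' @return The estimate with OR-scale fields filled in.
#' @export
to_odds_ratio <- function(est) {
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%-28s beta %7.4f (SE %.4f) 95%% CI [%7.4f, %7.4f] p = %.3g  (J = %d)\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$or)) {
    cat(sprintf("%-28s OR %.3f [%.3f, %.3f]\n", "", x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' Per-SNP Wald ratios
#'
#' ratio_j = beta_out_j / beta_exp_j with first-order delta-method SE
#' `se_out_j / |beta_exp_j|` (the exposure uncertainty is ignored, the
#' two-sample MR default).  `second_order = TRUE` adds the exposure term
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param h a harmonized set (dropped rows are excluded automatically).
#' @param second_order use the second-order SE (default `FALSE`).
#' @return A `ratio_set` data frame: `snp_id`, `ratio`, `ratio_se`,
#'   `weight` (= 1/ratio_se^2).
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  k <- harmonized_kept(h)
  if (any(k$beta_exp == 0)) {
    stop("zero exposure beta for SNP(s): ",
         paste(k$snp_id[k$beta_exp == 0], collapse = ", "), call. = FALSE)
  }
  ratio <- k$beta_out / k$beta_exp
  se <- if (second_order) {
    sqrt(k$se_out^2 / k$beta_exp^2 +
           k$beta_out^2 * k$se_exp^2 / k$beta_exp^4)
  } else {
    k$se_out / abs(k$beta_exp)
  }
  out <- data.frame(snp_id = k$snp_id, ratio = ratio, ratio_se = se,
                    weight = 1 / se^2, stringsAsFactors = FALSE)
  class(out) <- c("ratio_set", "data.frame")
  out
}

# closed-form fixed-effect IVW on a ratio set (theta, se)
ivw_fixed_core <- function(ratio, weight) {
  sw <- sum(weight)
  c(theta = sum(weight * ratio) / sw, se = 1 / sqrt(sw))
}

# Q contributions at theta
q_contributions <- function(ratio, weight, theta) weight * (ratio - theta)^2

#' Inverse-variance-weighted estimator
#'
#' Fixed effect: `theta = sum(w b)/sum(w)`, `se = sum(w)^(-1/2)` with
#' `w = 1/ratio_se^2`.  Multiplicative random effect: the same point
#' estimate with the SE inflated by `max(1, sqrt(Q/(J-1)))` (Cochran's Q at
#' the estimate).  Penalization multiplies each weight by
#' `min(1, 20 p_j)` where `p_j` is the upper-tail chi-square(1) p-value of
#' that SNP's Q contribution, re-solving iteratively.  The robust variant
#' fits a bisquare M-regression of the outcome betas on the exposure betas
#' through the origin (tuning constant 4.685, weights 1/se_out^2).
#'
#' @param h a harmonized set.
#' @param model `"fixed"` or `"random"` SE model.
#' @param penalized apply weight penalization.
#' @param robust use the redescending (bisquare) robust fit.
#' @param binary outcome is binary: report the OR scale (default `TRUE`).
#' @return An [mr_estimate()].
#' @export
mr_ivw <- function(h, model = c("fixed", "random"), penalized = FALSE,
                   robust = FALSE, binary = TRUE) {
  model <- match.arg(model)
  r <- wald_ratios(h)
  j <- nrow(r)
  if (j < 2) stop("IVW requires at least 2 SNPs", call. = FALSE)
  k <- harmonized_kept(h)
  w <- r$weight

  if (penalized) {
    # iterate: penalize weights by each SNP's Q-contribution p-value
    theta <- ivw_fixed_core(r$ratio, w)["theta"]
    for (it in seq_len(100)) {
      qj <- q_contributions(r$ratio, r$weight, theta)
      pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
      w <- r$weight * pmin(1, 20 * pj)
      theta_new <- if (robust) {
        robust_origin_fit(k, w)$theta
      } else {
        sum(w * r$ratio) / sum(w)
      }
      if (abs(theta_new - theta) < 1e-10) { theta <- theta_new; break }
      theta <- theta_new
    }
  }

  if (robust) {
    fit <- robust_origin_fit(k, w)
    theta <- fit$theta
    se <- fit$se
  } else {
    if (!penalized) {
      core <- ivw_fixed_core(r$ratio, w)
      theta <- core["theta"]
    }
    se <- 1 / sqrt(sum(w))
  }

  if (model == "random" && j >= 2) {
    qq <- sum(q_contributions(r$ratio, w, theta))
    se <- se * max(1, sqrt(qq / (j - 1)))
  }

  label <- paste0(if (penalized) "penalized " else "",
                  if (robust) "robust " else "",
                  "IVW (", model, ")")
  mr_estimate(label, unname(theta), unname(se), j, binary = binary)
}

# bisquare M-estimation of beta_out ~ 0 + beta_exp with prior weights w_out
# (on the outcome scale); returns theta and its (unscaled) SE
robust_origin_fit <- function(k, weight_ratio) {
  # translate ratio-scale weights back to outcome-scale prior weights:
  # w_ratio = beta_exp^2/se_out^2  =>  w_out = w_ratio/beta_exp^2
  w_out <- weight_ratio / k$beta_exp^2
  fit <- MASS::rlm(k$beta_out ~ 0 + k$beta_exp, weights = w_out,
                   psi = MASS::psi.bisquare, c = 4.685, maxit = 200)
  sm <- summary(fit)
  list(theta = unname(stats::coef(fit)[1]),
       se = unname(sm$coefficients[1, 2]))
}

#' MR-Egger regression
#'
#' Each SNP is oriented so its exposure beta is positive (both betas
#' flipped where needed), then the outcome betas are regressed on the
#' exposure betas with an intercept, weights 1/se_out^2.  SEs carry the
#' multiplicative random-effects scaling `max(1, sigma_resid)` where
#' `sigma_resid` is the weighted residual standard deviation.  The slope is
#' the pleiotropy-robust causal estimate under the InSIDE assumption; the
#' intercept with its z-test is the directional-pleiotropy test.
#'
#' @param h a harmonized set with at least 3 SNPs.
#' @param binary outcome is binary (OR scale on the slope).
#' @return List with `slope` and `intercept`, both [mr_estimate()]s.
#' @export
mr_egger <- function(h, binary = TRUE) {
  k <- harmonized_kept(h)
  j <- nrow(k)
  if (j < 3) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  s <- sign(k$beta_exp)
  x <- abs(k$beta_exp)
  y <- s * k$beta_out
  w <- 1 / k$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sigma <- summary(fit)$sigma            # weighted residual SD, df = J - 2
  scale <- max(1, sigma)
  X <- cbind(1, x)
  se_unscaled <- sqrt(diag(solve(crossprod(X, w * X))))
  co <- stats::coef(fit)
  slope <- mr_estimate("MR-Egger slope", unname(co[2]),
                       unname(se_unscaled[2] * scale), j, binary = binary)
  intercept <- mr_estimate("MR-Egger intercept", unname(co[1]),
                           unname(se_unscaled[1] * scale), j, binary = FALSE)
  list(slope = slope, intercept = intercept)
}

#' Simple and weighted median estimators
#'
#' Simple: the sample median of the Wald ratios.  Weighted: ratios sorted
#' ascending; with standardized cumulative weights
#' `s_j = (cumsum(w)_j - w_j/2)/sum(w)` the estimate interpolates ratio
#' against s at s = 0.5.  The SE is the standard deviation of the estimator
#' over `n_boot` parametric-bootstrap replicates, each redrawing
#' `beta_exp* ~ N(beta_exp, se_exp^2)` and `beta_out* ~ N(beta_out,
#' se_out^2)` and recomputing ratios, weights and the median.
#'
#' @param h a harmonized set with at least 3 SNPs.
#' @param weighting `"simple"` or `"weighted"`.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap (reproducible when supplied).
#' @param binary outcome is binary (OR scale).
#' @return An [mr_estimate()].
#' @export
mr_median <- function(h, weighting = c("simple", "weighted"),
                      n_boot = 10000, seed = NULL, binary = TRUE) {
  weighting <- match.arg(weighting)
  k <- harmonized_kept(h)
  j <- nrow(k)
  if (j < 3) stop("median estimator requires at least 3 SNPs", call. = FALSE)

  point <- median_core(k$beta_out / k$beta_exp,
                       (k$beta_exp / k$se_out)^2, weighting)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  bx <- matrix(stats::rnorm(j * n_boot, k$beta_exp, k$se_exp), nrow = j)
  by <- matrix(stats::rnorm(j * n_boot, k$beta_out, k$se_out), nrow = j)
  est <- vapply(seq_len(n_boot), function(b) {
    median_core(by[, b] / bx[, b], (bx[, b] / k$se_out)^2, weighting)
  }, numeric(1))
  se <- stats::sd(est)
  mr_estimate(paste(weighting, "median"), point, se, j, binary = binary)
}

median_core <- function(ratio, weight, weighting) {
  if (weighting == "simple") return(stats::median(ratio))
  o <- order(ratio)
  r <- ratio[o]; w <- weight[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Profile maximum-likelihood estimator
#'
#' Maximizes the Gaussian likelihood with independent errors over the true
#' causal effect and the J true SNP-exposure effects; profiling out the
#' latter reduces the (-2 log) likelihood to
#' `f(theta) = sum((beta_out - theta beta_exp)^2 / (se_out^2 + theta^2
#' se_exp^2))`, minimized numerically from the fixed-effect IVW start.  The
#' SE comes from the observed information (curvature of f at the optimum).
#'
#' @param h a harmonized set with at least 2 SNPs.
#' @param binary outcome is binary (OR scale).
#' @return An [mr_estimate()].
#' @export
mr_maxlik <- function(h, binary = TRUE) {
  k <- harmonized_kept(h)
  j <- nrow(k)
  if (j < 2) stop("maximum likelihood requires at least 2 SNPs", call. = FALSE)
  f <- function(th) {
    sum((k$beta_out - th * k$beta_exp)^2 / (k$se_out^2 + th^2 * k$se_exp^2))
  }
  start <- unname(ivw_fixed_core(k$beta_out / k$beta_exp,
                                 (k$beta_exp / k$se_out)^2)["theta"])
  opt <- stats::optim(start, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (opt$convergence != 0) {
    stop("maximum-likelihood optimizer failed to converge (code ",
         opt$convergence, "): ", opt$message %||% "", call. = FALSE)
  }
  theta <- opt$par
  hstep <- 1e-5 * max(1, abs(theta))
  fpp <- (f(theta + hstep) - 2 * f(theta) + f(theta - hstep)) / hstep^2
  if (!is.finite(fpp) || fpp <= 0) {
    stop("maximum-likelihood curvature non-positive at the optimum",
         call. = FALSE)
  }
  se <- sqrt(2 / fpp)                    # f is -2 log L up to a constant
  mr_estimate("maximum likelihood", theta, se, j, binary = binary)
}

#' Run the full estimator battery
#'
#' Fixed and multiplicative-random IVW, penalized IVW, penalized robust
#' IVW, maximum likelihood, simple and weighted medians, and the MR-Egger
#' slope: the eight-method sensitivity battery.
#'
#' @param h a harmonized set.
#' @param n_boot,seed bootstrap controls for the medians.
#' @param binary outcome is binary (OR scale).
#' @return A data frame with one row per method (method, beta, se, ci_low,
#'   ci_high, pval, n_snps, or, or_ci_low, or_ci_high).
#' @export
mr_all_methods <- function(h, n_boot = 10000, seed = NULL, binary = TRUE) {
  ests <- list(
    mr_ivw(h, "fixed", binary = binary),
    mr_ivw(h, "random", binary = binary),
    mr_ivw(h, "random", penalized = TRUE, binary = binary),
    mr_ivw(h, "random", penalized = TRUE, robust = TRUE, binary = binary),
    mr_maxlik(h, binary = binary),
    mr_median(h, "simple", n_boot = n_boot, seed = seed, binary = binary),
    mr_median(h, "weighted", n_boot = n_boot,
              seed = if (is.null(seed)) NULL else seed + 1L, binary = binary),
    mr_egger(h, binary = binary)$slope
  )
  estimates_frame(ests)
}

estimates_frame <- function(ests) {
  do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               n_snps = e$n_snps,
               or = e$or %||% NA_real_,
               or_ci_low = e$or_ci_low %||% NA_real_,
               or_ci_high = e$or_ci_high %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
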