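# Multivariable MR: joint weighted regression of the outcome betas on
# several exposures' betas, giving direct effects adjusted for the others.

#' Assemble a multivariable MR input
#'
#' Harmonizes the outcome and each covariate table onto the exposure's
#' effect-allele frame (same rules as [harmonize()]) and keeps the
#' row-complete SNP intersection.  Column 1 of the exposure-beta matrix is
#' always the primary exposure.
#'
#' @param exposure primary-exposure [association_table] (the instrument).
#' @param covariates one covariate [association_table] or a list of them.
#' @param outcome outcome [association_table].
#' @param palindrome_maf,palindrome_mode passed to [harmonize()].
#' @return An `mvmr_input`: list with `snp_id`, `beta_exp` (J x K matrix,
#'   exposure first), `se_exp` (matching SEs), `beta_out`, `se_out`,
#'   `exposures` (labels) and `n_dropped` per source.
#' @export
assemble_mvmr <- function(exposure, covariates, outcome,
                          palindrome_maf = 0.42,
                          palindrome_mode = c("both", "exposure-only")) {
  palindrome_mode <- match.arg(palindrome_mode)
  if (is.data.frame(covariates)) covariates <- list(covariates)
  k_exp <- 1 + length(covariates)

  hout <- harmonize(exposure, outcome, palindrome_maf, palindrome_mode)
  hcov <- lapply(covariates, function(cv)
    harmonize(exposure, cv, palindrome_maf, palindrome_mode))

  ok <- hout$action %in% c("kept", "sign_flipped")
  n_dropped <- list(outcome = sum(!ok))
  for (i in seq_along(hcov)) {
    oki <- hcov[[i]]$action %in% c("kept", "sign_flipped")
    n_dropped[[paste0("covariate_", i)]] <- sum(!oki)
    ok <- ok & oki
  }
  j <- sum(ok)
  if (j < k_exp + 2) {
    stop("only ", j, " complete SNPs for K = ", k_exp,
         " exposures: model underdetermined", call. = FALSE)
  }

  beta_exp <- cbind(hout$beta_exp[ok],
                    do.call(cbind, lapply(hcov, function(x) x$beta_out[ok])))
  se_exp <- cbind(hout$se_exp[ok],
                  do.call(cbind, lapply(hcov, function(x) x$se_out[ok])))
  labels <- c(trait_label(exposure),
              vapply(covariates, trait_label, character(1)))
  colnames(beta_exp) <- colnames(se_exp) <- labels

  out <- list(snp_id = hout$snp_id[ok],
              beta_exp = beta_exp, se_exp = se_exp,
              beta_out = hout$beta_out[ok], se_out = hout$se_out[ok],
              exposures = labels, n_dropped = n_dropped)
  class(out) <- "mvmr_input"
  out
}

#' Multivariable IVW estimator
#'
#' Weighted linear regression of the outcome betas on the K exposure-beta
#' columns without intercept, weights 1/se_out^2.  SEs use multiplicative
#' random-effects scaling floored at 1 (or the fixed model on request).
#' The first coefficient is the direct effect of the primary exposure
#' adjusted for the covariates; the remaining coefficients are labeled
#' secondary.
#'
#' @param m an `mvmr_input` from [assemble_mvmr()].
#' @param se_model `"random"` (default) or `"fixed"` SE scaling.
#' @param binary outcome is binary (OR scale).
#' @return A data frame with one row per exposure (primary first), in
#'   [mr_all_methods()] column layout plus a `role` column.
#' @export
mvmr_ivw <- function(m, se_model = c("random", "fixed"), binary = TRUE) {
  se_model <- match.arg(se_model)
  X <- m$beta_exp
  j <- nrow(X)
  # an all-zero covariate column carries no information: drop it from the
  # fit (its coefficient is reported as NA) so the primary estimate reduces
  # exactly to the univariable IVW
  zero_col <- colSums(abs(X)) == 0
  if (zero_col[1]) stop("primary exposure betas are all zero", call. = FALSE)
  X <- X[, !zero_col, drop = FALSE]
  kx <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < kx) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):kx]]
    stop("rank-deficient exposure design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- 1 / m$se_out^2
  xtwx <- crossprod(X, w * X)
  co <- solve(xtwx, crossprod(X, w * m$beta_out))[, 1]
  resid <- m$beta_out - X %*% co
  sigma2 <- sum(w * resid^2) / (j - kx)
  scale <- if (se_model == "random") max(1, sqrt(sigma2)) else 1
  se <- sqrt(diag(solve(xtwx))) * scale

  co_full <- se_full <- rep(NA_real_, length(zero_col))
  co_full[!zero_col] <- co
  se_full[!zero_col] <- se
  ests <- lapply(which(!zero_col), function(i) {
    mr_estimate(paste0("MVMR-IVW: ", m$exposures[i]), unname(co_full[i]),
                unname(se_full[i]), j, binary = binary)
  })
  out <- estimates_frame(ests)
  if (any(zero_col)) {
    na_rows <- do.call(rbind, lapply(which(zero_col), function(i) {
      data.frame(method = paste0("MVMR-IVW: ", m$exposures[i]),
                 beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, pval = NA_real_, n_snps = j,
                 or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, na_rows)
    out <- out[order(match(out$method, paste0("MVMR-IVW: ", m$exposures))), ]
    rownames(out) <- NULL
  }
  out$role <- c("primary", rep("secondary", length(m$exposures) - 1))
  out
}
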