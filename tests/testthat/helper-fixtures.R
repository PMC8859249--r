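# shared fixture builders; everything is generated in code at test time

# minimal association table from parallel vectors
make_table <- function(snp_id, beta, se, pval = NULL, eaf = 0.3,
                       effect_allele = "A", other_allele = "G",
                       chrom = "1", pos = NULL, label = "trait") {
  n <- length(snp_id)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(pos)) pos <- 1e6 + 2e7 * (seq_len(n) - 1)
  association_table(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, n), pos = pos,
    effect_allele = rep_len(effect_allele, n),
    other_allele = rep_len(other_allele, n),
    eaf = rep_len(eaf, n), beta = beta, se = se, pval = pval,
    n = rep_len(1e5, n), stringsAsFactors = FALSE), trait_label = label)
}

# random harmonized set drawn directly (independent of simulate_pair)
rand_h <- function(j, theta = -0.27, seed = NULL, se_x = 0.004, se_y = 0.015,
                   gamma_sd = 0.025) {
  if (!is.null(seed)) set.seed(seed)
  gamma <- rnorm(j, 0, gamma_sd) + 0.05 * sign(rnorm(j))
  sx <- rep_len(se_x, j) * runif(j, 0.8, 1.2)
  sy <- rep_len(se_y, j) * runif(j, 0.8, 1.2)
  harmonized_set(sprintf("rs%04d", seq_len(j)),
                 beta_exp = rnorm(j, gamma, sx), se_exp = sx,
                 beta_out = rnorm(j, theta * gamma, sy), se_out = sy)
}

# stack single-SNP association tables, optionally renaming the SNPs
rbind_tables <- function(..., ids = NULL) {
  tabs <- list(...)
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  if (!is.null(ids)) df$snp_id <- ids
  df$pos <- 1e6 + 2e7 * (seq_len(nrow(df)) - 1)
  association_table(df, trait_label(tabs[[1]]))
}

# independent WLS-through-origin route (explicit normal equations)
wls_origin_oracle <- function(x, y, w) {
  xtwx <- sum(w * x * x)
  theta <- sum(w * x * y) / xtwx
  list(theta = theta, se = sqrt(1 / xtwx))
}

# independent WLS-with-intercept route (matrix normal equations)
wls_intercept_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  co <- solve(A, t(X) %*% (w * y))
  list(coef = as.numeric(co), cov_unscaled = solve(A))
}
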