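# the causal-effect estimator battery

test_that("Wald ratios: arithmetic, symmetry, delta-method ordering", {
  h <- harmonized_set("rs1", beta_exp = 0.1, se_exp = 0.02,
                      beta_out = 0.05, se_out = 0.1)
  r <- wald_ratios(h)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$ratio_se, 1.0)
  expect_equal(r$weight, 1.0)

  # flipping both betas leaves the ratio unchanged
  h2 <- harmonized_set("rs1", -0.1, 0.02, -0.05, 0.1)
  expect_equal(wald_ratios(h2)$ratio, 0.5)

  # second-order SE dominates the first-order SE on random tables
  h3 <- rand_h(100, seed = 41)
  expect_true(all(wald_ratios(h3, second_order = TRUE)$ratio_se >=
                    wald_ratios(h3)$ratio_se))

  h4 <- harmonized_set(c("rs1", "rs2"), c(0.1, 0), c(0.02, 0.02),
                       c(0.05, 0.01), c(0.1, 0.1))
  expect_error(wald_ratios(h4), "rs2")
})

test_that("fixed-effect IVW is the inverse-variance meta-analysis", {
  h1 <- harmonized_set("rs1", 0.1, 0.02, 0.05, 0.1)
  expect_error(mr_ivw(h1), "at least 2")

  # two identical SNPs: theta = ratio, se = ratio_se / sqrt(2)
  h2 <- harmonized_set(c("rs1", "rs2"), c(0.1, 0.1), 0.02, c(0.05, 0.05), 0.1)
  est <- mr_ivw(h2, "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 1 / sqrt(2))
  expect_equal(est$n_snps, 2)

  # generic WLS-through-origin oracle with residual variance forced to 1
  h3 <- rand_h(50, seed = 43)
  est3 <- mr_ivw(h3, "fixed")
  o <- wls_origin_oracle(h3$beta_exp, h3$beta_out, 1 / h3$se_out^2)
  expect_equal(est3$beta, o$theta, tolerance = 1e-12)
  expect_equal(est3$se, o$se, tolerance = 1e-12)
})

test_that("multiplicative random-effect scaling is floored at one", {
  # heterogeneous data: random SE > fixed SE
  h <- rand_h(40, seed = 47)
  h$beta_out <- h$beta_out + rnorm(40, 0, 5) * h$se_out
  fixed <- mr_ivw(h, "fixed"); random <- mr_ivw(h, "random")
  expect_equal(random$beta, fixed$beta)
  r <- wald_ratios(h)
  q <- sum(r$weight * (r$ratio - fixed$beta)^2)
  expect_equal(random$se, fixed$se * sqrt(q / 39))

  # under-dispersed data: scale clips to 1, random == fixed
  h2 <- harmonized_set(sprintf("rs%d", 1:10), rep(0.1, 10), 0.02,
                       rep(0.05, 10) + seq(-1e-6, 1e-6, length.out = 10), 0.1)
  expect_equal(mr_ivw(h2, "random")$se, mr_ivw(h2, "fixed")$se)
})

test_that("penalized and robust IVW down-weight outliers", {
  set.seed(53)
  h <- rand_h(60, theta = -0.27, seed = 53)
  hc <- h
  out_idx <- 1:3
  hc$beta_out[out_idx] <- hc$beta_out[out_idx] + 12 * hc$se_out[out_idx]
  plain <- mr_ivw(hc, "fixed")
  pen <- mr_ivw(hc, "random", penalized = TRUE)
  rob <- mr_ivw(hc, "random", robust = TRUE)
  pen_rob <- mr_ivw(hc, "random", penalized = TRUE, robust = TRUE)
  clean <- mr_ivw(h, "fixed")
  # contaminated plain IVW is pulled away; penalized/robust recover
  expect_gt(abs(plain$beta - clean$beta), abs(pen$beta - clean$beta))
  expect_gt(abs(plain$beta - clean$beta), abs(rob$beta - clean$beta))
  expect_gt(abs(plain$beta - clean$beta), abs(pen_rob$beta - clean$beta))
  # penalization is deterministic: second run identical
  expect_identical(pen$beta, mr_ivw(hc, "random", penalized = TRUE)$beta)
  # on clean homogeneous data penalization changes little
  expect_equal(mr_ivw(h, "fixed", penalized = TRUE)$beta, clean$beta,
               tolerance = 0.05)
})

test_that("MR-Egger matches the weighted regression with intercept", {
  # exact-fit case: data on beta_out = 0.01 + 0.5 * beta_exp, equal se_out
  x <- seq(0.02, 0.1, length.out = 8)
  h <- harmonized_set(sprintf("rs%d", 1:8), x, 0.004, 0.01 + 0.5 * x, 0.05)
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)
  # perfect fit: residual scale clips to 1 -> unscaled WLS standard errors
  o <- wls_intercept_oracle(x, 0.01 + 0.5 * x, rep(1 / 0.05^2, 8))
  expect_equal(eg$slope$se, sqrt(o$cov_unscaled[2, 2]), tolerance = 1e-10)

  # random-data coefficients match the independent oracle after orientation
  h2 <- rand_h(45, seed = 59)
  h2$beta_exp[1:20] <- -h2$beta_exp[1:20]   # mixed orientations
  eg2 <- mr_egger(h2)
  s <- sign(h2$beta_exp)
  o2 <- wls_intercept_oracle(abs(h2$beta_exp), s * h2$beta_out,
                             1 / h2$se_out^2)
  expect_equal(eg2$intercept$beta, o2$coef[1], tolerance = 1e-12)
  expect_equal(eg2$slope$beta, o2$coef[2], tolerance = 1e-12)

  expect_error(mr_egger(harmonized_set(c("a", "b"), c(0.1, 0.2), 0.01,
                                       c(0.1, 0.2), 0.1)), "at least 3")
})

test_that("median estimators: symmetric case, degeneracy, determinism", {
  # ratios {0.1, 0.5, 0.9} with equal weights
  h <- harmonized_set(sprintf("rs%d", 1:3), rep(0.1, 3), 0.01,
                      c(0.01, 0.05, 0.09), 0.05)
  simple <- mr_median(h, "simple", n_boot = 200, seed = 1)
  weighted <- mr_median(h, "weighted", n_boot = 200, seed = 1)
  expect_equal(simple$beta, 0.5)
  expect_equal(weighted$beta, 0.5)

  # equal weights: weighted point estimate equals the simple median
  set.seed(61)
  h2 <- harmonized_set(sprintf("rs%d", 1:9), rep(0.08, 9), 0.004,
                       rnorm(9, -0.02, 0.01), 0.04)
  expect_equal(mr_median(h2, "weighted", n_boot = 100, seed = 2)$beta,
               mr_median(h2, "simple", n_boot = 100, seed = 2)$beta)

  # seeded bootstrap SEs reproduce exactly
  h3 <- rand_h(25, seed = 67)
  a <- mr_median(h3, "weighted", n_boot = 2000, seed = 7)
  b <- mr_median(h3, "weighted", n_boot = 2000, seed = 7)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)

  # point estimates live inside the ratio range
  r <- wald_ratios(h3)
  for (w in c("simple", "weighted")) {
    est <- mr_median(h3, w, n_boot = 100, seed = 3)
    expect_gte(est$beta, min(r$ratio))
    expect_lte(est$beta, max(r$ratio))
  }
})

test_that("maximum likelihood: IVW limit and grid-search oracle", {
  # exposure measured almost exactly: ML collapses to fixed-effect IVW
  h <- rand_h(30, seed = 71)
  h$se_exp <- rep(1e-10, 30)
  ml <- mr_maxlik(h)
  ivw <- mr_ivw(h, "fixed")
  expect_equal(ml$beta, ivw$beta, tolerance = 1e-6)
  expect_equal(ml$se, ivw$se, tolerance = 1e-4)

  # brute-force grid maximizer of the same profile objective
  for (seed in c(73, 79, 83)) {
    h2 <- rand_h(10, seed = seed)
    obj <- function(th) {
      sum((h2$beta_out - th * h2$beta_exp)^2 /
            (h2$se_out^2 + th^2 * h2$se_exp^2))
    }
    grid <- seq(-2, 2, length.out = 4001)
    for (pass in 1:4) {
      vals <- vapply(grid, obj, numeric(1))
      centre <- grid[which.min(vals)]
      half <- (grid[2] - grid[1]) * 2
      grid <- seq(centre - half, centre + half, length.out = 2001)
    }
    best <- grid[which.min(vapply(grid, obj, numeric(1)))]
    expect_equal(mr_maxlik(h2)$beta, best, tolerance = 1e-6)
  }
})

test_that("odds-ratio transform and estimate invariants", {
  est0 <- mr_estimate("x", 0, 0.1, 10, binary = TRUE)
  expect_equal(est0$or, 1.0)

  est <- mr_estimate("x", -0.274, 0.054, 121, binary = TRUE)
  expect_equal(est$or, 0.76, tolerance = 0.005)
  expect_equal(est$or_ci_low, 0.68, tolerance = 0.01)
  expect_equal(est$or_ci_high, 0.84, tolerance = 0.01)
  expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
  expect_true(est$pval > 0 && est$pval <= 1)

  # monotonicity of the transform
  ors <- vapply(seq(-1, 1, 0.25),
                function(b) mr_estimate("x", b, 0.1, 5, TRUE)$or, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("the battery returns the eight standard sensitivity methods", {
  h <- rand_h(40, seed = 89)
  est <- mr_all_methods(h, n_boot = 200, seed = 4)
  expect_equal(nrow(est), 8)
  expect_setequal(est$method,
                  c("IVW (fixed)", "IVW (random)", "penalized IVW (random)",
                    "penalized robust IVW (random)", "maximum likelihood",
                    "simple median", "weighted median", "MR-Egger slope"))
  expect_true(all(est$or > 0))
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
})
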