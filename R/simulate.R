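# Seeded synthetic summary-statistics generator.  Emulates a two-sample MR
# setting: J independent SNPs with true SNP-exposure effects gamma_j,
# SNP-outcome effects theta * gamma_j + alpha_j plus sampling noise, with
# configurable pleiotropy regimes (balanced, directional, InSIDE-violating),
# palindromic allele pairs, and optional gross outliers.  Defaults mirror
# the motivating study's scale: J = 121 instruments for a cognitive-trait
# exposure (GWAS n ~ 270k) against a binary cardiovascular outcome, with
# true log-OR theta = log(0.76) and outcome SEs sized so the fixed-IVW SE
# lands near 0.054.

#' Simulation configuration
#'
#' @param j_snps number of independent SNPs (default 121).
#' @param theta true causal effect, log-OR per SD of exposure
#'   (default `log(0.76)`).
#' @param gamma_sd spread of the true SNP-exposure effects (SD units per
#'   allele; default 0.025).  True effects are drawn from
#'   `N(0, gamma_sd^2)` truncated away from zero at `0.1 * gamma_sd` so
#'   Wald ratios stay well-defined.
#' @param se_exp_range,se_out_range sampling intervals for the exposure and
#'   outcome standard errors (defaults c(0.0008, 0.0015) and
#'   c(0.012, 0.018)).  The default exposure SEs keep mean instrument
#'   strength high (F of order several hundred) so the first-order Wald
#'   ratio's regression dilution stays negligible; weak-instrument regimes
#'   are a deliberate configuration extension, not the default.
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleio_mean,pleio_sd mean and SD of the direct (pleiotropic)
#'   effects alpha_j of invalid SNPs; `balanced` forces mean 0;
#'   `inside_violating` uses `alpha = inside_slope * gamma +
#'   N(pleio_mean, pleio_sd^2)` so instrument strength correlates with the
#'   direct effect.
#' @param prop_invalid fraction of SNPs carrying pleiotropy (in \[0,1\]).
#' @param inside_slope coupling constant c for the InSIDE-violating regime
#'   (default 1).
#' @param maf_range minor-allele-frequency sampling interval
#'   (default c(0.05, 0.5)).
#' @param palindrome_fraction fraction of SNPs given A/T or C/G allele
#'   pairs (default 0.2).
#' @param n_outliers number of gross outliers (default 0).
#' @param outlier_shift outlier displacement of the outcome beta in units
#'   of its SE (default 10).
#' @param seed RNG seed; the whole generator is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(j_snps = 121, theta = log(0.76), gamma_sd = 0.025,
                       se_exp_range = c(0.0008, 0.0015),
                       se_out_range = c(0.012, 0.018),
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleio_mean = 0, pleio_sd = 0, prop_invalid = 0,
                       inside_slope = 1, maf_range = c(0.05, 0.5),
                       palindrome_fraction = 0.2, n_outliers = 0,
                       outlier_shift = 10, seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(j_snps >= 1, gamma_sd > 0, all(se_exp_range > 0),
            all(se_out_range > 0), prop_invalid >= 0, prop_invalid <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            n_outliers >= 0)
  if (pleiotropy_mode == "balanced") pleio_mean <- 0
  cfg <- list(j_snps = j_snps, theta = theta, gamma_sd = gamma_sd,
              se_exp_range = se_exp_range, se_out_range = se_out_range,
              pleiotropy_mode = pleiotropy_mode, pleio_mean = pleio_mean,
              pleio_sd = pleio_sd, prop_invalid = prop_invalid,
              inside_slope = inside_slope, maf_range = maf_range,
              palindrome_fraction = palindrome_fraction,
              n_outliers = n_outliers, outlier_shift = outlier_shift,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

NONPALIN_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
PALIN_PAIRS <- list(c("A", "T"), c("C", "G"))

#' Simulate an exposure/outcome summary-statistics pair
#'
#' Generative model: `gamma_j ~ N(0, gamma_sd^2)` truncated at
#' `|gamma| >= 0.1 gamma_sd`; `beta_exp_j ~ N(gamma_j, se_exp_j^2)`;
#' `alpha_j = 0` for valid SNPs, else per the pleiotropy regime;
#' `beta_out_j ~ N(theta gamma_j + alpha_j, se_out_j^2)`, with
#' `n_outliers` SNPs additionally shifted by `outlier_shift * se_out_j`.
#' Both tables share allele codes, frequencies and positions (positions are
#' spaced beyond the default clump window so the SNPs are independent).
#'
#' @param cfg a [sim_config()].
#' @return List with `exposure` and `outcome` [association_table]s and
#'   `truth` (every latent value: gamma, alpha, valid/outlier flags,
#'   theta), sufficient to recompute all observables.
#' @export
simulate_pair <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  j <- cfg$j_snps

  gamma <- stats::rnorm(j, 0, cfg$gamma_sd)
  low <- abs(gamma) < 0.1 * cfg$gamma_sd
  while (any(low)) {    # rejection-sample the truncation
    gamma[low] <- stats::rnorm(sum(low), 0, cfg$gamma_sd)
    low <- abs(gamma) < 0.1 * cfg$gamma_sd
  }
  se_x <- stats::runif(j, cfg$se_exp_range[1], cfg$se_exp_range[2])
  se_y <- stats::runif(j, cfg$se_out_range[1], cfg$se_out_range[2])

  invalid <- rep(FALSE, j)
  n_inv <- round(cfg$prop_invalid * j)
  if (cfg$pleiotropy_mode != "none" && n_inv > 0) {
    invalid[sample.int(j, n_inv)] <- TRUE
  }
  alpha <- numeric(j)
  if (any(invalid)) {
    alpha[invalid] <- switch(
      cfg$pleiotropy_mode,
      balanced = stats::rnorm(sum(invalid), 0, cfg$pleio_sd),
      directional = stats::rnorm(sum(invalid), cfg$pleio_mean, cfg$pleio_sd),
      inside_violating = cfg$inside_slope * gamma[invalid] +
        stats::rnorm(sum(invalid), cfg$pleio_mean, cfg$pleio_sd),
      numeric(sum(invalid)))
  }

  beta_exp <- stats::rnorm(j, gamma, se_x)
  beta_out <- stats::rnorm(j, cfg$theta * gamma + alpha, se_y)
  outlier_ids <- integer(0)
  if (cfg$n_outliers > 0) {
    outlier_ids <- sample.int(j, min(cfg$n_outliers, j))
    beta_out[outlier_ids] <- beta_out[outlier_ids] +
      cfg$outlier_shift * se_y[outlier_ids]
  }

  palin <- stats::runif(j) < cfg$palindrome_fraction
  pairs <- lapply(seq_len(j), function(i) {
    pool <- if (palin[i]) PALIN_PAIRS else NONPALIN_PAIRS
    p <- pool[[sample.int(length(pool), 1)]]
    if (stats::runif(1) < 0.5) rev(p) else p
  })
  maf <- stats::runif(j, cfg$maf_range[1], cfg$maf_range[2])
  eaf <- ifelse(stats::runif(j) < 0.5, maf, 1 - maf)

  snp_id <- sprintf("rs%06d", seq_len(j))
  chrom <- as.character(rep_len(1:22, j))
  pos <- 1e6 + 2e7 * (seq_len(j) - 1) %/% 22   # same-chrom spacing 20 Mb

  mk <- function(beta, se, label, n) {
    association_table(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = vapply(pairs, `[`, character(1), 1),
      other_allele = vapply(pairs, `[`, character(1), 2),
      eaf = eaf, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
      stringsAsFactors = FALSE), trait_label = label)
  }
  list(exposure = mk(beta_exp, se_x, "simulated_exposure", 269867),
       outcome = mk(beta_out, se_y, "simulated_outcome", 184305),
       truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                    invalid = invalid, outlier_idx = outlier_ids,
                    se_exp = se_x, se_out = se_y, snp_id = snp_id,
                    config = cfg))
}

#' Simulate a SNP-trait annotation table
#'
#' Flagged SNPs receive one confounder-trait row with a genome-wide
#' significant p-value; a random subset of the remaining SNPs receives
#' innocuous-trait rows at non-significant p so the confounder-exclusion
#' filter has realistic negatives.
#'
#' @param table an [association_table] (the instrument candidates).
#' @param flagged_ids SNP ids to mark as confounder-associated (must be a
#'   subset of the table's ids).
#' @param confounder_traits trait names to sample flags from.
#' @param seed RNG seed.
#' @return A [trait_annotation_table].
#' @export
simulate_annotation_table <- function(table, flagged_ids,
                                      confounder_traits = c(
                                        "body mass index", "height", "weight",
                                        "waist circumference",
                                        "cholesterol level", "blood pressure",
                                        "diabetes", "alcohol intake",
                                        "smoking"),
                                      seed = NULL) {
  stopifnot(all(flagged_ids %in% table$snp_id))
  if (!is.null(seed)) set.seed(seed)
  n_f <- length(flagged_ids)
  rows <- data.frame(snp_id = character(0), trait_name = character(0),
                     pval = numeric(0), stringsAsFactors = FALSE)
  if (n_f > 0) {
    rows <- data.frame(
      snp_id = flagged_ids,
      trait_name = sample(confounder_traits, n_f, replace = TRUE),
      pval = 10^stats::runif(n_f, -20, -7.35),   # always < 5e-8
      stringsAsFactors = FALSE)
  }
  others <- setdiff(table$snp_id, flagged_ids)
  if (length(others)) {
    pick <- others[stats::runif(length(others)) < 0.5]
    if (length(pick)) {
      rows <- rbind(rows, data.frame(
        snp_id = pick,
        trait_name = sample(c("educational attainment", "reaction time",
                              "household income"), length(pick),
                            replace = TRUE),
        pval = 10^stats::runif(length(pick), -6, -1),
        stringsAsFactors = FALSE))
    }
  }
  trait_annotation_table(rows)
}

#' Simulate an LD table with block structure
#'
#' Assigns the first `sum(block_structure)` SNPs of the table to
#' consecutive LD blocks: within-block pairs get `r2 = within_r2` and
#' cross-block pairs are absent (r2 = 0 on lookup).  Positions of block
#' members are rewritten onto one chromosome with 1 kb spacing so each
#' block sits inside the default clump window; remaining SNPs keep their
#' positions.
#'
#' @param table an [association_table]; blocks are formed over its leading
#'   SNPs in order.
#' @param block_structure integer vector of block sizes
#'   (`sum <= nrow(table)`).
#' @param within_r2 r-squared assigned to within-block pairs.
#' @return List with `ld` (an [ld_table]) and `table` (the repositioned
#'   association table).
#' @export
simulate_ld_table <- function(table, block_structure, within_r2) {
  stopifnot(sum(block_structure) <= nrow(table))
  idx <- 1L
  pos <- table$pos
  chrom <- table$chrom
  rows <- list()
  for (b in seq_along(block_structure)) {
    size <- block_structure[b]
    members <- idx:(idx + size - 1L)
    chrom[members] <- as.character(b)
    pos[members] <- 1e6 + 1000 * seq_len(size)
    if (size >= 2) {
      cmb <- utils::combn(members, 2)
      rows[[b]] <- data.frame(snp_a = table$snp_id[cmb[1, ]],
                              snp_b = table$snp_id[cmb[2, ]],
                              r2 = within_r2, stringsAsFactors = FALSE)
    }
    idx <- idx + size
  }
  # unblocked SNPs move to private chromosomes so they never fall in-window
  if (idx <= nrow(table)) {
    rest <- idx:nrow(table)
    chrom[rest] <- as.character(length(block_structure) + seq_along(rest))
  }
  tab <- as.data.frame(table)
  tab$chrom <- chrom
  tab$pos <- pos
  out <- association_table(tab, trait_label = trait_label(table),
                           metadata = attr(table, "metadata"))
  ld <- if (length(rows)) {
    ld_table(do.call(rbind, rows))
  } else {
    ld_table(data.frame(snp_a = character(0), snp_b = character(0),
                        r2 = numeric(0)))
  }
  list(ld = ld, table = out)
}
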