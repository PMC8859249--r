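# Allele harmonization: align exposure and outcome tables onto the
# exposure's effect-allele frame, producing the estimator-ready set.

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table onto the exposure's effect-allele frame by
#' `snp_id`.  For each exposure SNP:
#' * absent from the outcome -> `dropped_missing`;
#' * same allele pair, same orientation -> `kept`;
#' * same pair, swapped orientation -> `sign_flipped` (outcome beta negated,
#'   eaf complemented);
#' * palindromic (A/T, C/G) pairs are kept only when strand can be inferred
#'   from allele frequencies: the MAF must be below `palindrome_maf` in the
#'   exposure (and, under `palindrome_mode = "both"`, also in the outcome)
#'   and the effect allele must be on the same side of 0.5 in both tables
#'   after letter alignment; otherwise `dropped_palindrome`;
#' * any other allele pair -> `dropped_allele_mismatch`.
#'
#' @param exposure,outcome [association_table]s for the exposure and the
#'   outcome trait.
#' @param palindrome_maf MAF cutoff below which a palindromic SNP is
#'   inferrable (default 0.42).
#' @param palindrome_mode apply the inferability cutoff to the exposure only
#'   or to both tables (default `"both"`, the conservative standard).
#' @return A `harmonized_set`: data frame with `snp_id`, aligned alleles,
#'   `eaf_exp`, `beta_exp`, `se_exp`, `eaf_out`, `beta_out`, `se_out` and an
#'   `action` column; estimators consume the `kept`/`sign_flipped` rows
#'   (see [harmonized_kept()]).
#' @export
harmonize <- function(exposure, outcome, palindrome_maf = 0.42,
                      palindrome_mode = c("both", "exposure-only")) {
  palindrome_mode <- match.arg(palindrome_mode)
  oidx <- match(exposure$snp_id, outcome$snp_id)
  if (all(is.na(oidx))) stop("no overlapping instruments", call. = FALSE)

  n <- nrow(exposure)
  action <- character(n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- oidx[i]
    if (is.na(j)) { action[i] <- "dropped_missing"; next }
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    eb <- outcome$effect_allele[j]; ob <- outcome$other_allele[j]
    if (ea == eb && oa == ob) {
      flip <- FALSE
    } else if (ea == ob && oa == eb) {
      flip <- TRUE
    } else {
      action[i] <- "dropped_allele_mismatch"; next
    }
    b_out <- if (flip) -outcome$beta[j] else outcome$beta[j]
    f_out <- if (flip) 1 - outcome$eaf[j] else outcome$eaf[j]

    pair <- paste(min(ea, oa), max(ea, oa))
    if (pair %in% c("A T", "C G")) {
      maf_exp <- pmin(exposure$eaf[i], 1 - exposure$eaf[i])
      maf_out <- pmin(f_out, 1 - f_out)
      inferrable <- !is.na(maf_exp) && maf_exp < palindrome_maf
      if (palindrome_mode == "both") {
        inferrable <- inferrable && !is.na(maf_out) && maf_out < palindrome_maf
      }
      concordant <- !is.na(exposure$eaf[i]) && !is.na(f_out) &&
        (exposure$eaf[i] - 0.5) * (f_out - 0.5) > 0
      if (!inferrable || !concordant) {
        action[i] <- "dropped_palindrome"; next
      }
    }
    action[i] <- if (flip) "sign_flipped" else "kept"
    beta_out[i] <- b_out
    se_out[i] <- outcome$se[j]
    eaf_out[i] <- f_out
  }

  out <- data.frame(snp_id = exposure$snp_id,
                    effect_allele = exposure$effect_allele,
                    other_allele = exposure$other_allele,
                    eaf_exp = exposure$eaf,
                    beta_exp = exposure$beta,
                    se_exp = exposure$se,
                    eaf_out = eaf_out,
                    beta_out = beta_out,
                    se_out = se_out,
                    action = action,
                    stringsAsFactors = FALSE)
  attr(out, "exposure_label") <- trait_label(exposure)
  attr(out, "outcome_label") <- trait_label(outcome)
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Extract the estimator-ready rows of a harmonized set
#'
#' @param h a `harmonized_set` from [harmonize()].
#' @return The rows with action `kept` or `sign_flipped`, i.e. the aligned
#'   (beta_exp, se_exp, beta_out, se_out) quadruples all estimators consume.
#' @export
harmonized_kept <- function(h) {
  out <- as.data.frame(h)[h$action %in% c("kept", "sign_flipped"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Build a harmonized set from already-aligned summary data
#'
#' For data whose effect alleles are already on a shared frame (e.g. a
#' published per-SNP instrument table): wraps the aligned beta/SE vectors
#' into the structure every estimator consumes, bypassing [harmonize()].
#'
#' @param snp_id SNP identifiers.
#' @param beta_exp,se_exp SNP-exposure associations and SEs (> 0).
#' @param beta_out,se_out SNP-outcome associations and SEs (> 0).
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @return A `harmonized_set` with all rows marked `kept`.
#' @export
harmonized_set <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_) {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  out <- data.frame(snp_id = as.character(snp_id),
                    effect_allele = NA_character_, other_allele = NA_character_,
                    eaf_exp = eaf_exp, beta_exp = beta_exp, se_exp = se_exp,
                    eaf_out = eaf_out, beta_out = beta_out, se_out = se_out,
                    action = "kept", stringsAsFactors = FALSE)
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(x$action)
  cat("harmonized_set:", nrow(x), "SNPs (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
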