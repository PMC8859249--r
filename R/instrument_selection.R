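# Instrument construction: genome-wide significance, MAF QC, palindromic-SNP
# classification, greedy LD clumping, confounder-association exclusion.
# Each filter returns the surviving table; clumping and confounder exclusion
# additionally return a selection audit (stage label -> n_in, n_removed,
# removed ids) so counts always reconcile.

new_audit_stage <- function(stage, n_in, removed_ids, detail = NULL) {
  out <- list(stage = stage, n_in = n_in, n_removed = length(removed_ids),
              n_out = n_in - length(removed_ids),
              removed_snp_ids = as.character(removed_ids))
  if (!is.null(detail)) out$detail <- detail
  out
}

#' Keep genome-wide significant associations
#'
#' Retains records with `pval < p_threshold` (strict inequality; a SNP at
#' exactly the threshold is removed).
#'
#' @param table an [association_table] with `pval` present for all records.
#' @param p_threshold significance threshold (default 5e-8).
#' @return The filtered `association_table` with an `audit` attribute.
#' @export
filter_significance <- function(table, p_threshold = 5e-8) {
  if (nrow(table) && anyNA(table$pval)) {
    stop("pval required for all records before significance filtering",
         call. = FALSE)
  }
  keep <- if (nrow(table)) table$pval < p_threshold else logical(0)
  out <- subset_assoc(table, keep)
  attr(out, "audit") <- new_audit_stage("significance", nrow(table),
                                        table$snp_id[!keep])
  out
}

#' Keep common variants by minor-allele frequency
#'
#' Retains records with `min(eaf, 1 - eaf) > maf_threshold` (strict).
#' Records lacking `eaf` pass unchanged but their ids are flagged in the
#' audit detail.
#'
#' @param table an [association_table].
#' @param maf_threshold minimum minor-allele frequency (default 0.01).
#' @return The filtered `association_table` with an `audit` attribute.
#' @export
filter_maf <- function(table, maf_threshold = 0.01) {
  maf <- pmin(table$eaf, 1 - table$eaf)
  keep <- is.na(maf) | maf > maf_threshold
  out <- subset_assoc(table, keep)
  attr(out, "audit") <- new_audit_stage(
    "maf", nrow(table), table$snp_id[!keep],
    detail = list(missing_eaf_passed = table$snp_id[is.na(maf)]))
  out
}

#' Classify a SNP's palindrome status
#'
#' A SNP is palindromic when its allele pair is A/T or C/G: the strand
#' cannot be inferred from the alleles alone.  A palindromic SNP is
#' inferrable when its minor-allele frequency is below `maf_cutoff`
#' (strict), and ambiguous otherwise — including when `eaf` is missing.
#'
#' @param effect_allele,other_allele allele characters (vectorized).
#' @param eaf effect-allele frequency (may be `NA`).
#' @param maf_cutoff MAF below which a palindrome is inferrable
#'   (default 0.42).
#' @return Character vector in `not_palindromic`, `palindromic_inferrable`,
#'   `palindromic_ambiguous`.
#' @export
classify_palindrome <- function(effect_allele, other_allele, eaf,
                                maf_cutoff = 0.42) {
  pair <- paste(pmin(effect_allele, other_allele),
                pmax(effect_allele, other_allele))
  palin <- pair %in% c("A T", "C G")
  maf <- pmin(eaf, 1 - eaf)
  out <- rep("not_palindromic", length(palin))
  out[palin] <- ifelse(!is.na(maf[palin]) & maf[palin] < maf_cutoff,
                       "palindromic_inferrable", "palindromic_ambiguous")
  out
}

#' Remove strand-ambiguous palindromic SNPs
#'
#' Drops records classified `palindromic_ambiguous` by
#' [classify_palindrome()] (MAF at or above the cutoff, or missing `eaf`).
#'
#' @inheritParams filter_maf
#' @param maf_cutoff palindrome inferability cutoff (default 0.42).
#' @return The filtered `association_table` with an `audit` attribute.
#' @export
filter_palindromes <- function(table, maf_cutoff = 0.42) {
  cls <- classify_palindrome(table$effect_allele, table$other_allele,
                             table$eaf, maf_cutoff)
  keep <- cls != "palindromic_ambiguous"
  out <- subset_assoc(table, keep)
  attr(out, "audit") <- new_audit_stage("palindrome", nrow(table),
                                        table$snp_id[!keep])
  out
}

#' Greedy LD clumping
#'
#' Standard p-value-seeded greedy clumping: SNPs are visited in ascending
#' p-value order (ties broken by `snp_id`); each accepted SNP removes every
#' remaining SNP on the same chromosome within `window_kb` kilobases whose
#' r-squared with it is at or above `r2_threshold`.  Pairs absent from the
#' LD table count as r2 = 0 (a warning tally is kept in the audit).  SNPs
#' farther apart than the window are never pruned regardless of the listed
#' r2.
#'
#' @param table an [association_table] with `pval`, `chrom`, `pos`.
#' @param ld an [ld_table] (or `NULL` for no LD information).
#' @param r2_threshold pruning threshold on r-squared (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return List with `table` (survivors in original order) and `audit`.
#' @export
ld_clump <- function(table, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  if (nrow(table) && (anyNA(table$pval) || anyNA(table$pos) || anyNA(table$chrom))) {
    stop("pval, chrom and pos are required for clumping", call. = FALSE)
  }
  ord <- order(table$pval, table$snp_id)
  active <- rep(TRUE, nrow(table))
  accepted <- logical(nrow(table))
  n_missing_pairs <- 0L
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!active[i]) next
    accepted[i] <- TRUE
    active[i] <- FALSE
    cand <- which(active & table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_bp)
    for (j in cand) {
      r2 <- ld_r2(ld, table$snp_id[i], table$snp_id[j])
      if (is.null(ld) ||
          !any((ld$snp_a == table$snp_id[i] & ld$snp_b == table$snp_id[j]) |
               (ld$snp_a == table$snp_id[j] & ld$snp_b == table$snp_id[i]))) {
        n_missing_pairs <- n_missing_pairs + 1L
      }
      if (r2 >= r2_threshold) active[j] <- FALSE
    }
  }
  out <- subset_assoc(table, accepted)
  audit <- new_audit_stage("ld_clump", nrow(table), table$snp_id[!accepted],
                           detail = list(n_missing_ld_pairs = n_missing_pairs))
  if (n_missing_pairs > 0) {
    warning(n_missing_pairs,
            " in-window SNP pair(s) absent from the LD table; treated as r2 = 0",
            call. = FALSE)
  }
  list(table = out, audit = audit)
}

#' Exclude SNPs associated with confounder traits
#'
#' A SNP is removed when it carries at least one annotation row whose trait
#' (case-insensitive match) is in `confounder_traits` with
#' `pval < p_threshold`.  The audit lists removed ids per trait.
#'
#' @param table an [association_table].
#' @param annotations a [trait_annotation_table].
#' @param confounder_traits character vector of trait names to exclude on.
#' @param p_threshold annotation significance threshold (default 5e-8).
#' @return List with `table` and `audit`.
#' @export
exclude_confounder_associated <- function(table, annotations,
                                          confounder_traits,
                                          p_threshold = 5e-8) {
  traits <- tolower(trimws(confounder_traits))
  ann <- annotations[tolower(trimws(annotations$trait_name)) %in% traits &
                       annotations$pval < p_threshold, , drop = FALSE]
  remove_ids <- unique(ann$snp_id[ann$snp_id %in% table$snp_id])
  per_trait <- lapply(split(ann$snp_id, tolower(trimws(ann$trait_name))),
                      function(ids) sort(unique(ids[ids %in% table$snp_id])))
  keep <- !(table$snp_id %in% remove_ids)
  out <- subset_assoc(table, keep)
  audit <- new_audit_stage("confounder_exclusion", nrow(table),
                           table$snp_id[!keep],
                           detail = list(removed_by_trait = per_trait))
  list(table = out, audit = audit)
}

#' Run the full instrument-selection pipeline
#'
#' Applies, in order: significance filter, MAF filter, palindrome filter,
#' LD clumping, and (when annotations are supplied) confounder exclusion,
#' collecting a per-stage selection-audit record.
#'
#' @inheritParams ld_clump
#' @inheritParams exclude_confounder_associated
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param maf_threshold MAF QC threshold (default 0.01).
#' @param palindrome_maf palindrome inferability cutoff (default 0.42).
#' @return List with `table` (the selected instrument) and `audit`
#'   (ordered list of stage records).
#' @export
select_instruments <- function(table, ld = NULL, annotations = NULL,
                               confounder_traits = NULL,
                               p_threshold = 5e-8, maf_threshold = 0.01,
                               palindrome_maf = 0.42, r2_threshold = 0.001,
                               window_kb = 10000) {
  audit <- list()
  t1 <- filter_significance(table, p_threshold)
  audit$significance <- attr(t1, "audit")
  t2 <- filter_maf(t1, maf_threshold)
  audit$maf <- attr(t2, "audit")
  t3 <- filter_palindromes(t2, palindrome_maf)
  audit$palindrome <- attr(t3, "audit")
  cl <- ld_clump(t3, ld, r2_threshold, window_kb)
  audit$ld_clump <- cl$audit
  t4 <- cl$table
  if (!is.null(annotations) && !is.null(confounder_traits)) {
    ex <- exclude_confounder_associated(t4, annotations, confounder_traits,
                                        p_threshold)
    audit$confounder_exclusion <- ex$audit
    t4 <- ex$table
  }
  list(table = t4, audit = audit)
}
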