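VALID_ALLELES <- c("A", "C", "G", "T")

ASSOC_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")

#' Construct a per-trait GWAS summary-association table
#'
#' An `association_table` is a data frame with one row per SNP and the
#' columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`.  `beta` is the per-allele association on the
#' analysis scale (SD units for a continuous trait, log-odds for a binary
#' trait) and `se` its standard error.  `eaf` (effect-allele frequency) and
#' `n` may be `NA`.  Rows violating the invariants (`se > 0`, alleles in
#' A/C/G/T and distinct, `eaf` in (0,1) when present, `pval` in (0,1]) are
#' dropped with counts recorded in the table metadata; duplicated `snp_id`s
#' keep the smallest p-value.
#'
#' @param df data frame carrying (at least) the association columns.
#' @param trait_label character scalar naming the trait.
#' @param metadata named list of free-form provenance (ancestry, build, ...).
#' @return An `association_table`: the validated data frame with attributes
#'   `trait_label` and `metadata` (including `n_dropped`).
#' @export
association_table <- function(df, trait_label, metadata = list()) {
  stopifnot(is.data.frame(df), is.character(trait_label), length(trait_label) == 1)
  for (col in c("snp_id", "effect_allele", "other_allele", "beta", "se")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing: ", col, call. = FALSE)
    }
  }
  for (col in setdiff(ASSOC_COLS, names(df))) df[[col]] <- NA
  df <- df[ASSOC_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  n_in <- nrow(df)
  drop_reasons <- character(0)

  bad_allele <- !(df$effect_allele %in% VALID_ALLELES) |
    !(df$other_allele %in% VALID_ALLELES) |
    df$effect_allele == df$other_allele
  bad_num <- is.na(df$beta) | is.na(df$se) | df$se <= 0 |
    (!is.na(df$pval) & (df$pval <= 0 | df$pval > 1)) |
    (!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1))
  bad <- bad_allele | bad_num | is.na(df$snp_id) | df$snp_id == ""
  if (any(bad)) {
    drop_reasons <- c(drop_reasons,
                      n_invalid_allele = sum(bad_allele),
                      n_invalid_numeric = sum(bad_num & !bad_allele))
    df <- df[!bad, , drop = FALSE]
  }

  # duplicated rsIDs: keep the smallest p-value (NA p sorts last)
  if (anyDuplicated(df$snp_id)) {
    ord <- order(df$snp_id, ifelse(is.na(df$pval), Inf, df$pval))
    dfo <- df[ord, , drop = FALSE]
    keep <- !duplicated(dfo$snp_id)
    n_dup <- sum(!keep)
    df <- dfo[keep, , drop = FALSE]
    df <- df[order(match(df$snp_id, unique(dfo$snp_id))), , drop = FALSE]
    metadata$n_duplicates_dropped <- n_dup
  }

  rownames(df) <- NULL
  metadata$n_dropped <- n_in - nrow(df) -
    (metadata$n_duplicates_dropped %||% 0)
  attr(df, "trait_label") <- trait_label
  attr(df, "metadata") <- metadata
  class(df) <- c("association_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("association_table '%s': %d SNPs (%d dropped on ingest)\n",
              trait_label(x), nrow(x),
              attr(x, "metadata")$n_dropped %||% 0))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname association_table
#' @param x an `association_table`.
#' @export
trait_label <- function(x) attr(x, "trait_label")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated file with a header line (the delimiter is
#' auto-detected from the header) and maps source column names onto the
#' canonical association columns.  Rows failing the table invariants are
#' dropped and counted in the metadata under `n_dropped`.
#'
#' @param path path to a TSV/CSV file with header.
#' @param column_map named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column headers.  Canonical
#'   headers already present in the file need not be mapped.
#' @param trait_label trait name stored on the table.
#' @return An [association_table].
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column '", src, "' (for ", canon, ") absent from ", path,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_mand <- setdiff(c("snp_id", "effect_allele", "other_allele", "beta", "se"),
                          names(df))
  if (length(missing_mand)) {
    stop("mandatory column missing: ", paste(missing_mand, collapse = ", "),
         call. = FALSE)
  }
  association_table(df, trait_label = trait_label,
                    metadata = list(source = path))
}

#' Write a table or report to disk
#'
#' Association tables, harmonized sets and estimate tables are written as
#' TSV with a deterministic column order; numeric columns are serialized
#' with 12 significant digits so a write/read round trip preserves values
#' to well under 1e-9 relative error.  Lists (reports) are written as JSON.
#'
#' @param x an `association_table`, `harmonized_set`, data frame, or a list
#'   (report); estimate tables carrying an `or` column serialize both the
#'   beta scale and the OR scale.
#' @param path destination path.
#' @export
write_table <- function(x, path) {
  if (is.data.frame(x)) {
    out <- as.data.frame(x)
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                             sprintf("%.12g", out[[col]]))
      }
    }
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed to write ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else if (is.list(x)) {
    jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    stop("unsupported object for write_table", call. = FALSE)
  }
  invisible(path)
}

# recursively drop S3 classes (except data.frame) so reports serialize
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Pairwise linkage-disequilibrium table
#'
#' Rows of `(snp_a, snp_b, r2)`.  Lookups are symmetric and unlisted pairs
#' default to r2 = 0.
#'
#' @param df data frame with columns `snp_a`, `snp_b`, `r2` (each r2 in
#'   \[0,1\]).
#' @return An `ld_table`.
#' @export
ld_table <- function(df) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(df)))
  df$snp_a <- as.character(df$snp_a)
  df$snp_b <- as.character(df$snp_b)
  df$r2 <- as.numeric(df$r2)
  if (any(is.na(df$r2) | df$r2 < 0 | df$r2 > 1)) {
    stop("r2 values must lie in [0,1]", call. = FALSE)
  }
  class(df) <- c("ld_table", "data.frame")
  df
}

# symmetric r2 lookup for one pair; 0 when unlisted
ld_r2 <- function(ld, a, b) {
  if (is.null(ld) || nrow(ld) == 0) return(0)
  hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
  if (any(hit)) max(ld$r2[hit]) else 0
}

#' SNP-to-trait annotation table (PhenoScanner-style lookups)
#'
#' @param df data frame with columns `snp_id`, `trait_name`, `pval`
#'   (p in (0,1\]).
#' @return A `trait_annotation_table`.
#' @export
trait_annotation_table <- function(df) {
  stopifnot(all(c("snp_id", "trait_name", "pval") %in% names(df)))
  df$snp_id <- as.character(df$snp_id)
  df$trait_name <- as.character(df$trait_name)
  df$pval <- as.numeric(df$pval)
  if (any(is.na(df$pval) | df$pval <= 0 | df$pval > 1)) {
    stop("annotation pval must lie in (0,1]", call. = FALSE)
  }
  class(df) <- c("trait_annotation_table", "data.frame")
  df
}

# keep the association_table class (and attrs) through [-subsetting of rows
subset_assoc <- function(tab, keep) {
  out <- as.data.frame(tab)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_label") <- attr(tab, "trait_label")
  attr(out, "metadata") <- attr(tab, "metadata")
  class(out) <- c("association_table", "data.frame")
  out
}
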