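# the four instrument-construction filters and their audits

test_that("significance filter uses strict inequality at 5e-8", {
  tab <- make_table(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                    se = 0.01, pval = c(4.9e-8, 5e-8, 1e-10))
  out <- filter_significance(tab)
  expect_setequal(out$snp_id, c("rs1", "rs3"))
  expect_equal(attr(out, "audit")$removed_snp_ids, "rs2")

  empty <- make_table(character(0), numeric(0), numeric(0))
  expect_equal(nrow(filter_significance(empty)), 0)
})

test_that("simulated lead-SNP sets are counted exactly", {
  # 242 lead SNPs of which 30 sit at or above genome-wide significance
  set.seed(11)
  pv <- c(10^runif(212, -40, -7.4), 10^runif(30, -7.2, -2))
  pv[213] <- 5e-8                      # boundary value, must be removed
  tab <- make_table(sprintf("rs%03d", 1:242), beta = 0.02, se = 0.003,
                    pval = sample(pv))
  expect_equal(nrow(filter_significance(tab)), 212)
})

test_that("MAF filter matches a brute-force per-row check", {
  tab <- make_table(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                    eaf = c(0.995, 0.5))
  out <- filter_maf(tab)
  expect_equal(out$snp_id, "rs2")      # MAF 0.005 removed, 0.5 kept

  set.seed(7)
  j <- 200
  tab2 <- make_table(sprintf("rs%03d", 1:j), beta = 0.1, se = 0.01,
                     eaf = runif(j, 0.001, 0.999))
  keep_oracle <- vapply(seq_len(j), function(i) {
    min(tab2$eaf[i], 1 - tab2$eaf[i]) > 0.01
  }, logical(1))
  expect_equal(filter_maf(tab2)$snp_id, tab2$snp_id[keep_oracle])
})

test_that("palindrome classification follows the 0.42 MAF rule", {
  expect_equal(classify_palindrome("A", "T", 0.30), "palindromic_inferrable")
  expect_equal(classify_palindrome("A", "T", 0.50), "palindromic_ambiguous")
  expect_equal(classify_palindrome("A", "T", 0.42), "palindromic_ambiguous")
  expect_equal(classify_palindrome("A", "G", 0.50), "not_palindromic")
  expect_equal(classify_palindrome("G", "C", 0.70), "palindromic_inferrable")
  expect_equal(classify_palindrome("C", "G", NA_real_),
               "palindromic_ambiguous")
  # filter drops only the ambiguous class
  tab <- make_table(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                    effect_allele = c("A", "A", "A"),
                    other_allele = c("T", "T", "G"),
                    eaf = c(0.30, 0.50, 0.50))
  expect_setequal(filter_palindromes(tab)$snp_id, c("rs1", "rs3"))
})

test_that("LD clumping keeps the best SNP per correlated in-window group", {
  tab <- make_table(c("rsA", "rsB"), beta = 0.1, se = 0.01,
                    pval = c(1e-10, 1e-9), pos = c(100000, 105000))
  ld <- ld_table(data.frame(snp_a = "rsA", snp_b = "rsB", r2 = 0.5))
  out <- ld_clump(tab, ld)
  expect_equal(out$table$snp_id, "rsA")
  expect_equal(out$audit$removed_snp_ids, "rsB")

  # distance rule gates first: cross-chromosome r2 is irrelevant
  tab2 <- make_table(c("rsA", "rsB"), beta = 0.1, se = 0.01,
                     pval = c(1e-10, 1e-9), chrom = c("1", "2"),
                     pos = c(100000, 100000))
  ld2 <- ld_table(data.frame(snp_a = "rsA", snp_b = "rsB", r2 = 0.9))
  expect_equal(nrow(ld_clump(tab2, ld2)$table), 2)

  # same chromosome but outside the 10,000 kb window: both kept
  tab3 <- make_table(c("rsA", "rsB"), beta = 0.1, se = 0.01,
                     pval = c(1e-10, 1e-9), pos = c(1e6, 1e6 + 1.1e7))
  expect_equal(nrow(ld_clump(tab3, ld2)$table), 2)
})

test_that("clumping matches an exhaustive pairwise-check oracle on blocks", {
  set.seed(13)
  j <- 20
  tab <- make_table(sprintf("rs%02d", 1:j), beta = 0.05, se = 0.005,
                    pval = 10^runif(j, -30, -8))
  blk <- simulate_ld_table(tab, block_structure = c(5, 4, 3), within_r2 = 0.6)

  # independent greedy route: explicit r2 matrix + repeated scans
  tb <- as.data.frame(blk$table)
  r2m <- matrix(0, j, j, dimnames = list(tb$snp_id, tb$snp_id))
  for (r in seq_len(nrow(blk$ld))) {
    r2m[blk$ld$snp_a[r], blk$ld$snp_b[r]] <- blk$ld$r2[r]
    r2m[blk$ld$snp_b[r], blk$ld$snp_a[r]] <- blk$ld$r2[r]
  }
  remaining <- tb$snp_id
  kept <- character(0)
  while (length(remaining)) {
    sub <- tb[tb$snp_id %in% remaining, ]
    best <- sub$snp_id[order(sub$pval, sub$snp_id)][1]
    kept <- c(kept, best)
    bi <- match(best, tb$snp_id)
    prune <- vapply(remaining, function(s) {
      si <- match(s, tb$snp_id)
      tb$chrom[si] == tb$chrom[bi] &&
        abs(tb$pos[si] - tb$pos[bi]) <= 1e7 && r2m[best, s] >= 0.001
    }, logical(1))
    remaining <- setdiff(remaining[!prune], best)
  }
  got <- ld_clump(blk$table, blk$ld)$table
  expect_setequal(got$snp_id, kept)
  # no retained pair violates the (same-chrom, in-window, r2) rule
  if (nrow(got) > 1) {
    cmb <- combn(nrow(got), 2)
    viol <- apply(cmb, 2, function(ix) {
      got$chrom[ix[1]] == got$chrom[ix[2]] &&
        abs(got$pos[ix[1]] - got$pos[ix[2]]) <= 1e7 &&
        r2m[got$snp_id[ix[1]], got$snp_id[ix[2]]] >= 0.001
    })
    expect_false(any(viol))
  }
})

test_that("confounder exclusion removes annotated SNPs per trait", {
  tab <- make_table(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01)
  ann <- trait_annotation_table(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    trait_name = c("Body Mass Index", "educational attainment", "smoking"),
    pval = c(1e-12, 1e-20, 1e-6)))
  out <- exclude_confounder_associated(
    tab, ann, c("body mass index", "smoking"))
  # rs1 removed (trait listed, significant); rs2 trait not listed;
  # rs3 listed but p >= 5e-8
  expect_setequal(out$table$snp_id, c("rs2", "rs3"))
  expect_equal(out$audit$detail$removed_by_trait[["body mass index"]], "rs1")
})

test_that("the 157 -> 121 confounder-exclusion reconstruction holds", {
  set.seed(99)
  j <- 157
  tab <- make_table(sprintf("rs%03d", 1:j), beta = 0.02, se = 0.003,
                    pval = 10^runif(j, -30, -8))
  flagged <- sample(tab$snp_id, 36)
  ann <- simulate_annotation_table(tab, flagged, seed = 100)
  out <- exclude_confounder_associated(tab, ann,
                                       confounder_traits = c(
                                         "body mass index", "height",
                                         "weight", "waist circumference",
                                         "cholesterol level",
                                         "blood pressure", "diabetes",
                                         "alcohol intake", "smoking"))
  expect_equal(nrow(out$table), 121)
  expect_equal(out$audit$n_removed, 36)
  expect_setequal(out$audit$removed_snp_ids, flagged)
})

test_that("filters are idempotent and audits reconcile", {
  set.seed(21)
  j <- 80
  tab <- make_table(sprintf("rs%02d", 1:j), beta = rnorm(j, 0, 0.03),
                    se = 0.004, pval = 10^runif(j, -12, -4),
                    eaf = runif(j, 0.001, 0.999),
                    effect_allele = sample(c("A", "C"), j, TRUE),
                    other_allele = sample(c("T", "G"), j, TRUE))
  for (f in list(function(x) filter_significance(x),
                 function(x) filter_maf(x),
                 function(x) filter_palindromes(x))) {
    once <- f(tab)
    twice <- f(once)
    expect_equal(twice$snp_id, once$snp_id)
    aud <- attr(once, "audit")
    expect_equal(aud$n_in - aud$n_removed, nrow(once))
    expect_equal(attr(twice, "audit")$n_removed, 0)
  }
  sel <- select_instruments(tab)
  stages <- sel$audit
  for (i in seq_along(stages)[-1]) {
    expect_equal(stages[[i]]$n_in, stages[[i - 1]]$n_out)
  }
  expect_equal(stages[[length(stages)]]$n_out, nrow(sel$table))
})
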