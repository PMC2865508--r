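test_that("proportion_below uses a strict threshold", {
  expect_equal(proportion_below(c(0.01, 0.2, 0.04, 0.8)), 0.5)
  p101 <- c(rep(0.01, 37), rep(0.5, 64))
  expect_equal(round(100 * proportion_below(p101), 2), 36.63)
  expect_equal(proportion_below(rep(1, 10)), 0)
  expect_equal(proportion_below(c(0.05, 0.06)), 0)   # strict inequality
  expect_error(proportion_below(numeric()), "empty")
})

test_that("matched draws reproduce the focal stratum histogram", {
  st <- small_study()
  keys <- match_keys(st$panel$snps, st$panel$genes, st$panel$geno)
  set.seed(5)
  focal_ids <- sample(keys$snp_id, 60)
  focal <- keys[keys$snp_id %in% focal_ids, ]
  focal$mode <- ifelse(focal$proximal, "cis", "trans")
  hist_of <- function(tab, ids) {
    rows <- tab[match(ids, tab$snp_id), ]
    table(factor(rows$maf_bin, 1:5),
          factor(ifelse(rows$proximal, "cis", "trans"), c("cis", "trans")))
  }
  ref <- table(factor(focal$maf_bin, 1:5), factor(focal$mode, c("cis", "trans")))
  for (i in 1:25) {
    ids <- draw_matched_set(focal, keys)
    expect_equal(length(ids), nrow(focal))
    expect_false(anyDuplicated(ids) > 0)
    drawn <- keys[match(ids, keys$snp_id), ]
    # trans slots may land on proximal SNPs; only bins must agree exactly,
    # and cis slots must be covered by proximal SNPs bin-by-bin
    expect_equal(unname(table(factor(drawn$maf_bin, 1:5))),
                 unname(table(factor(focal$maf_bin, 1:5))))
    for (b in 1:5) {
      need_cis <- sum(focal$maf_bin == b & focal$mode == "cis")
      expect_gte(sum(drawn$maf_bin == b & drawn$proximal), need_cis)
    }
  }
})

test_that("LD multiplicity is honoured and infeasible strata error clearly", {
  # panel with tight blocks so groups of correlated SNPs exist
  cfg <- sim_config(seed = 19, n_snps = 300, n_samples = 400, n_genes = 60,
                    within_block_r = 0.97, block_sizes = 3L)
  pan <- simulate_genotypes(cfg)
  keys <- match_keys(pan$snps, pan$genes, pan$geno)
  grp_sizes <- table(keys$ld_group)
  g3 <- as.integer(names(grp_sizes)[grp_sizes == 3][1])
  focal <- keys[keys$ld_group == g3, ]
  focal$mode <- ifelse(focal$proximal, "cis", "trans")
  for (i in 1:10) {
    ids <- draw_matched_set(focal, keys)
    expect_equal(length(unique(keys$ld_group[match(ids, keys$snp_id)])), 1L)
  }
  # stratum with no pool support errors with the stratum named
  bad <- focal[1, ]
  bad$maf_bin <- setdiff(1:5, keys$maf_bin)[1]
  if (!is.na(bad$maf_bin))
    expect_error(draw_matched_set(bad, keys), "infeasible stratum")
})

test_that("empirical p follows the add-one rule and the null mean tracks alpha", {
  st <- small_study()
  keys <- match_keys(st$panel$snps, st$panel$genes, st$panel$geno)
  # craft a GWAS where only the focal SNPs are significant
  set.seed(6)
  focal_ids <- sample(keys$snp_id[keys$proximal], 10)
  gwas <- data.frame(snp_id = keys$snp_id,
                     p = ifelse(keys$snp_id %in% focal_ids, 1e-6, 0.9))
  res <- enrichment_test(focal_ids, keys, gwas, n_iter = 999, seed = 2)
  expect_equal(res$observed_prop, 1)
  expect_equal(res$p_empirical, 1 / 1000)
  expect_equal(res$fold, res$observed_prop / res$null_mean)
  expect_equal(res$ci95[2] - res$null_mean, 1.96 * res$null_sd)

  # uniform GWAS: null mean approaches alpha
  set.seed(8)
  gwas_u <- data.frame(snp_id = keys$snp_id, p = runif(nrow(keys)))
  focal_u <- sample(keys$snp_id, 150)
  res_u <- enrichment_test(focal_u, keys, gwas_u, n_iter = 10000, seed = 3)
  expect_lt(abs(res_u$null_mean - 0.05), 0.012)
})

test_that("z, CI and the normal-tail approximation are mutually consistent", {
  st <- small_study()
  keys <- match_keys(st$panel$snps, st$panel$genes, st$panel$geno)
  res <- enrichment_test(unique(keys$snp_id[1:80]), keys, st$gwas,
                         n_iter = 2000, seed = 4)
  expect_equal(res$z, (res$observed_prop - res$null_mean) / res$null_sd)
  expect_equal(res$p_approx, pnorm(res$z, lower.tail = FALSE))
  expect_gte(res$p_empirical, 1 / (res$n_iter + 1))
})

test_that("expanded-set mode matches total size within the tolerance window", {
  cfg <- sim_config(seed = 23, n_snps = 400, n_samples = 500, n_genes = 80,
                    within_block_r = 0.95, block_sizes = 4L)
  pan <- simulate_genotypes(cfg)
  keys <- match_keys(pan$snps, pan$genes, pan$geno)
  set.seed(9)
  gwas <- data.frame(snp_id = keys$snp_id, p = runif(nrow(keys)))
  set.seed(10)
  focal <- sample(keys$snp_id, 40)
  res <- enrichment_test(focal, keys, gwas, n_iter = 200, seed = 5,
                         expand = list(geno = pan$geno, size_tol = 0.10))
  ex <- expand_set(focal, pan$geno, pan$snps)
  expect_equal(res$n_snps, length(ex$expanded_set))
  expect_gt(res$n_snps, length(focal))
})

test_that("compare_sets handles nesting, extremes and the degenerate case", {
  st <- small_study()
  keys <- match_keys(st$panel$snps, st$panel$genes, st$panel$geno)
  set.seed(12)
  background <- keys[keys$snp_id %in% sample(keys$snp_id, 120), ]
  gwas_u <- data.frame(snp_id = keys$snp_id, p = runif(nrow(keys)))

  # degenerate: focal = background -> every draw ties the observed value
  res_d <- suppressWarnings(compare_sets(background$snp_id, background,
                                         gwas_u, n_iter = 200, seed = 6))
  expect_equal(res_d$p, 1)

  # focal holds every significant SNP of the background -> minimal p
  sig_ids <- background$snp_id[gwas_u$p[match(background$snp_id,
                                              gwas_u$snp_id)] < 0.05]
  focal2 <- c(sig_ids, sample(setdiff(background$snp_id, sig_ids), 3))
  res_m <- compare_sets(focal2, background, gwas_u, n_iter = 499, seed = 7)
  expect_lte(res_m$p, 0.05)

  # non-nested focal warns
  outsider <- setdiff(keys$snp_id, background$snp_id)[1]
  expect_warning(compare_sets(c(background$snp_id[1:5], outsider),
                              keys, gwas_u, n_iter = 50, seed = 8),
                 regexp = NA)
  expect_warning(compare_sets(c(background$snp_id[1:5], outsider),
                              background[-1, ], gwas_u, n_iter = 50, seed = 8),
                 "not nested")
})

test_that("focal SNPs without GWAS scores are dropped with a message", {
  st <- small_study()
  keys <- match_keys(st$panel$snps, st$panel$genes, st$panel$geno)
  gwas_part <- st$gwas[-(1:40), ]
  focal <- keys$snp_id[c(1:5, 50:60)]
  expect_message(
    res <- enrichment_test(focal, keys, gwas_part, n_iter = 100, seed = 9),
    "without GWAS scores")
})
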