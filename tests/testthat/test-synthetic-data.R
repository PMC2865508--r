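test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_snps = 60, n_samples = 50, n_genes = 20,
                    cross_spec = modifyList(sim_config()$cross_spec,
                                            list(n_f2 = 60L)))
  a <- simulate_genotypes(cfg); b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(a$geno, a$snps, a$genes, cfg)
  eb <- simulate_expression(b$geno, b$snps, b$genes, cfg)
  expect_identical(ea, eb)
  ga <- simulate_gwas(a$geno, a$snps, cfg)
  gb <- simulate_gwas(b$geno, b$snps, cfg)
  expect_identical(ga, gb)
  expect_identical(simulate_f2_cross(cfg), simulate_f2_cross(cfg))
})

test_that("panel MAFs respect the configured range and match realized frequencies", {
  cfg <- sim_config(seed = 5, n_snps = 500, n_samples = 2000, n_genes = 50)
  panel <- simulate_genotypes(cfg)
  expect_true(all(panel$snps$maf > cfg$maf_range[1]))
  expect_true(all(panel$snps$maf < cfg$maf_range[2]))
  dev <- abs(colMeans(panel$geno) / 2 - panel$snps$maf)
  expect_lt(mean(dev), 0.01)
  expect_gt(mean(dev <= 0.02), 0.98)
  # block sizes sum to the SNP count
  expect_identical(sum(table(panel$snps$block)), nrow(panel$snps))
})

test_that("within-block genotype correlation is calibrated to the target", {
  # independence case
  cfg0 <- sim_config(seed = 2, n_snps = 40, n_samples = 2000, n_genes = 20,
                     n_chromosomes = 1L, within_block_r = 0, block_sizes = 10L)
  p0 <- simulate_genotypes(cfg0)
  r0 <- abs(cor(p0$geno[, p0$snps$block == 1]))
  expect_lt(mean(r0[upper.tri(r0)]), 0.05)

  # strong-LD case: every within-block pair above 0.89 in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 100 + s, n_snps = 10, n_samples = 2000,
                      n_genes = 8, n_chromosomes = 1L,
                      within_block_r = 0.95, block_sizes = 10L)
    p <- simulate_genotypes(cfg)
    r <- abs(cor(p$geno))
    all(r[upper.tri(r)] > 0.89)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0), "positive integer")
  expect_error(sim_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(module_spec = list(sizes = 10L, loadings = 1.2,
                                             causal_effect = 0)),
               "loadings")
})

test_that("null expression gives uniform Kruskal-Wallis p-values", {
  cfg <- sim_config(seed = 8, n_snps = 250, n_samples = 200, n_genes = 20,
                    cis_effect = 0, esnp_frac = 0, module_spec = NULL,
                    within_block_r = 0, block_sizes = 1L)
  panel <- simulate_genotypes(cfg)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, cfg)
  rank_mat <- apply(expr, 2, rank)
  tie_corr <- rep(1, ncol(expr))
  ps <- unlist(lapply(seq_len(ncol(panel$geno)), function(j)
    esnpnet:::kw_matrix(panel$geno[, j], rank_mat, tie_corr)))
  expect_equal(length(ps), 5000)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("zero loadings leave modules uncorrelated", {
  cfg <- sim_config(seed = 9, n_snps = 60, n_samples = 400, n_genes = 60,
                    cis_effect = 0, esnp_frac = 0,
                    module_spec = list(sizes = c(20L, 20L),
                                       loadings = c(0, 0), causal_effect = 0.5))
  panel <- simulate_genotypes(cfg)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, cfg)
  mods <- attr(expr, "modules")
  g1 <- mods$gene_id[mods$module == 1]; g2 <- mods$gene_id[mods$module == 2]
  cc <- cor(expr[, g1], expr[, g2])
  expect_lt(mean(abs(cc)), 0.07)
})

test_that("designated cis pairs are recoverable at high power", {
  cfg <- sim_config(seed = 13, n_snps = 300, n_samples = 400, n_genes = 80,
                    cis_effect = 1, esnp_frac = 0.3, module_spec = NULL)
  panel <- simulate_genotypes(cfg)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, cfg)
  es <- map_esnps(panel$geno, panel$snps, expr, panel$genes, n_perm = 10,
                  seed = 1)
  truth <- attr(expr, "esnp_pairs")
  blk <- setNames(panel$snps$block, panel$snps$snp_id)
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(es$gene_id == truth$gene_id[i] &
          blk[es$snp_id] == blk[truth$snp_id[i]]), TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("a cis-violating designated pair is rejected", {
  st <- small_study()
  far <- st$panel$snps$snp_id[st$panel$snps$chrom == "chr2"][1]
  g1 <- st$panel$genes$gene_id[st$panel$genes$chrom == "chr1"][1]
  expect_error(
    simulate_expression(st$panel$geno, st$panel$snps, st$panel$genes, st$cfg,
                        pairs = data.frame(snp_id = far, gene_id = g1)),
    "cis rule")
})

test_that("null GWAS p-values are uniform and the chi-square matches chisq.test", {
  cfg <- sim_config(seed = 21, n_snps = 400, n_samples = 50, n_genes = 20,
                    gwas_spec = list(n_gwas_samples = 2000L,
                                     liability_effect = 0, prevalence = 0.2,
                                     test = "genotype"))
  panel <- simulate_genotypes(cfg)
  gwas <- simulate_gwas(panel$geno, panel$snps, cfg)
  prop <- mean(gwas$p < 0.05)
  ci <- qbinom(c(0.005, 0.995), nrow(gwas), 0.05) / nrow(gwas)
  expect_gte(prop, ci[1]); expect_lte(prop, ci[2])

  # vectorized statistic agrees with stats::chisq.test
  set.seed(4)
  g <- matrix(sample(0:2, 600, TRUE), 200, 3)
  case <- sample(c(TRUE, FALSE), 200, TRUE)
  mine <- esnpnet:::genotype_chisq_p(g, case)
  ref <- apply(g, 2, function(col)
    suppressWarnings(chisq.test(table(case, col), correct = FALSE)$p.value))
  expect_equal(mine, unname(ref), tolerance = 1e-12)
})

test_that("module-driving SNPs carry GWAS signal under a liability effect", {
  cfg <- sim_config(seed = 31, n_snps = 300, n_samples = 100, n_genes = 100,
                    gwas_spec = list(n_gwas_samples = 5000L,
                                     liability_effect = 0.3, prevalence = 0.2,
                                     test = "genotype"))
  panel <- simulate_genotypes(cfg)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, cfg)
  drv <- attr(expr, "drivers")$snp_id
  gwas <- simulate_gwas(panel$geno, panel$snps, cfg, driver_snps = drv)
  sig_blocks <- panel$snps$block[match(drv, panel$snps$snp_id)]
  in_sig <- panel$snps$block %in% sig_blocks
  expect_lt(median(gwas$p[in_sig]), median(gwas$p[!in_sig]))
})

test_that("F2 genotypes are Mendelian and map violations are rejected", {
  cfg <- sim_config(seed = 17,
                    cross_spec = list(n_f2 = 5000L, spacing_cM = 20,
                                      chrom_length_cM = 60, n_chromosomes = 1L,
                                      model = "causal", b_LG = 0, b_GT = 0,
                                      sd_G = 1, sd_T = 1, n_noise_genes = 0L))
  cross <- simulate_f2_cross(cfg)
  for (m in colnames(cross$geno)) {
    tab <- tabulate(cross$geno[, m] + 1L, 3)
    expect_gt(chisq.test(tab, p = c(1, 2, 1) / 4)$p.value, 0.001)
  }
  # zero spacing: adjacent markers identical
  cfg0 <- sim_config(seed = 18,
                     cross_spec = modifyList(cfg$cross_spec,
                                             list(n_f2 = 200L, spacing_cM = 0)))
  cr0 <- simulate_f2_cross(cfg0)
  expect_identical(unname(cr0$geno[, 1]), unname(cr0$geno[, 2]))
  expect_error(simulate_f2_cross(
    sim_config(cross_spec = modifyList(cfg$cross_spec, list(spacing_cM = -1)))),
    "spacing")
})
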