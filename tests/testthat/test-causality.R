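cross_cfg <- function(seed, model = "causal", n_f2 = 500L, b_LG = 0.7,
                      b_GT = 0.7, n_chrom = 4L, spacing = 10) {
  sim_config(seed = seed,
             cross_spec = list(n_f2 = n_f2, spacing_cM = spacing,
                               chrom_length_cM = 50, n_chromosomes = n_chrom,
                               model = model, b_LG = b_LG, b_GT = b_GT,
                               sd_G = 1, sd_T = 1, n_noise_genes = 0L))
}

test_that("LOD scan peaks at the driving marker and matches the closed form", {
  cross <- simulate_f2_cross(cross_cfg(1))
  trait <- cross$geno[, cross$truth$locus] - 1     # exactly the additive code
  lods <- qtl_scan(cross, trait)
  expect_equal(lods$marker[which.max(lods$lod)], cross$truth$locus)
  off_chrom <- lods$lod[lods$chrom != "chr1"]
  expect_lt(max(off_chrom), 2)

  # closed-form identity: LOD = -(n/2) log10(1 - R^2)
  y <- cross$traits$insulin
  g <- cross$geno[, 5]
  a <- g - 1; d <- as.numeric(g == 1)
  r2 <- summary(lm(y ~ a + d))$r.squared
  lod_ref <- -(length(y) / 2) * log10(1 - r2)
  lods_y <- qtl_scan(cross, y)
  expect_equal(lods_y$lod[5], lod_ref, tolerance = 1e-10)
})

test_that("LOD curves are invariant to affine transforms of the trait", {
  cross <- simulate_f2_cross(cross_cfg(2))
  l1 <- qtl_scan(cross, cross$traits$insulin)
  l2 <- qtl_scan(cross, 3 - 2.5 * cross$traits$insulin)
  expect_equal(l1$lod, l2$lod, tolerance = 1e-10)
  expect_error(qtl_scan(cross, rep(1, nrow(cross$geno))), "constant")
})

test_that("null traits rarely exceed LOD 4 anywhere on the genome", {
  clean <- vapply(1:50, function(s) {
    cross <- simulate_f2_cross(cross_cfg(100 + s, b_LG = 0, b_GT = 0))
    set.seed(s)
    max(qtl_scan(cross, rnorm(nrow(cross$geno)))$lod) < 4
  }, TRUE)
  expect_gte(mean(clean), 0.95)
})

test_that("forward stepwise recovers planted QTL and respects its controls", {
  found <- vapply(1:50, function(s) {
    cross <- simulate_f2_cross(cross_cfg(200 + s, b_LG = 0, b_GT = 0))
    set.seed(s)
    m1 <- "c1.m03"; m2 <- "c2.m04"
    trait <- 0.8 * (cross$geno[, m1] - 1) + 0.5 * (cross$geno[, m2] - 1) +
      rnorm(nrow(cross$geno))
    sel <- forward_stepwise_qtl(cross, trait)
    near <- function(target) {
      t_row <- cross$map[cross$map$marker == target, ]
      any(sel$chrom == t_row$chrom & abs(sel$cM - t_row$cM) <= 10)
    }
    near(m1) && near(m2)
  }, TRUE)
  expect_gte(mean(found), 0.9)

  empty <- vapply(1:20, function(s) {
    cross <- simulate_f2_cross(cross_cfg(300 + s, b_LG = 0, b_GT = 0))
    set.seed(s)
    nrow(forward_stepwise_qtl(cross, rnorm(nrow(cross$geno)))) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.95)

  cross <- simulate_f2_cross(cross_cfg(4))
  expect_lte(nrow(forward_stepwise_qtl(cross, cross$traits$insulin,
                                       max_qtl = 1)), 1)
  # threshold monotonicity: a stricter threshold selects a subset
  lo <- forward_stepwise_qtl(cross, cross$traits$insulin, lod_threshold = 1.5)
  hi <- forward_stepwise_qtl(cross, cross$traits$insulin, lod_threshold = 4)
  expect_true(all(hi$marker %in% lo$marker))
})

test_that("pleiotropy test is calibrated under the null and powered under signal", {
  null_p <- vapply(1:200, function(s) {
    set.seed(s)
    g <- rbinom(200, 2, 0.5)
    pleiotropy_test(g, rnorm(200), rnorm(200))$p
  }, 0)
  expect_gt(ks.test(null_p, "punif")$p.value, 0.01)

  sig <- vapply(1:50, function(s) {
    set.seed(500 + s)
    g <- rbinom(500, 2, 0.5)
    a <- g - 1
    pleiotropy_test(g, 0.5 * a + rnorm(500), 0.5 * a + rnorm(500))$p < 0.001
  }, TRUE)
  expect_gte(mean(sig), 0.95)

  # robust to strong trait correlation without marker effect
  rej <- vapply(1:200, function(s) {
    set.seed(700 + s)
    g <- rbinom(300, 2, 0.5)
    z <- rnorm(300)
    t1 <- z + 0.46 * rnorm(300)            # cor(t1, t2) ~ 0.9
    t2 <- z + 0.46 * rnorm(300)
    pleiotropy_test(g, t1, t2)$p < 0.05
  }, TRUE)
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(mean(rej), ci[1]); expect_lte(mean(rej), ci[2])

  g <- rbinom(100, 2, 0.5); y <- rnorm(100)
  expect_error(pleiotropy_test(g, y, y), "identical traits")
})

test_that("model selection is symmetric under swapping G and T", {
  set.seed(9)
  g <- rbinom(400, 2, 0.4)
  G <- 0.7 * (g - 1) + rnorm(400)
  T_ <- 0.7 * G + rnorm(400)
  fwd <- causal_model_select(g, G, T_)
  swp <- causal_model_select(g, T_, G)
  expect_equal(fwd$model, "causal")
  expect_equal(swp$model, "reactive")
  expect_equal(unname(fwd$aic["causal"]), unname(swp$aic["reactive"]))
  expect_equal(unname(fwd$aic["independent"]), unname(swp$aic["independent"]))
  expect_error(causal_model_select(g, rep(1, 400), T_), "degenerate")
})

test_that("the three-criteria filter reproduces the published-count fixture", {
  # 159-gene module; 117 linked to the interval; 8 with strong cis-eQTL
  # inside it; 5 of those causal; exactly 1 with a significant human cis
  # eSNP at p = 0.002
  genes <- sprintf("mg%03d", 1:159)
  cis8 <- genes[1:8]
  eq <- data.frame(gene_id = genes,
                   chrom = "chr9",
                   pos = c(rep(70e6, 8), rep(70e6, 109), rep(20e6, 42)),
                   lod = c(rep(5, 8), rep(1, 151)))
  causal5 <- cis8[1:5]
  causal_tab <- data.frame(gene_id = c(causal5, genes[30:40]),
                           trait = "insulin", model = "causal",
                           margin = 5)
  orth <- data.frame(mouse_id = genes, human_id = toupper(genes))
  esnps <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                      gene_id = toupper(c(causal5[3], causal5[4], genes[100])),
                      mode = "cis", fdr_pass = TRUE)
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     p = c(0.002, 0.5, 0.001))
  hit <- candidate_filter(genes, eq, causal_tab,
                          interval = list(chrom = "chr9", start = 65e6,
                                          stop = 95e6),
                          human_esnps = esnps, gwas = gwas, orthologs = orth)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gene_id, causal5[3])
  expect_equal(hit$p_t2d, 0.002)

  # no gene passes criterion 3 -> empty result
  gwas_null <- within(gwas, p <- rep(0.9, 3))
  expect_equal(nrow(candidate_filter(genes, eq, causal_tab,
                                     list(chrom = "chr9", start = 65e6,
                                          stop = 95e6),
                                     esnps, gwas_null, orth)), 0L)
})

test_that("an end-to-end planted causal gene is recovered from synthetic data", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 900 + s, n_snps = 200, n_samples = 250,
                      n_genes = 60,
                      gwas_spec = list(n_gwas_samples = 3000L,
                                       liability_effect = 0.5,
                                       prevalence = 0.2, test = "genotype"),
                      cross_spec = list(n_f2 = 400L, spacing_cM = 10,
                                        chrom_length_cM = 50,
                                        n_chromosomes = 2L, model = "causal",
                                        b_LG = 0.7, b_GT = 0.7, sd_G = 1,
                                        sd_T = 1, n_noise_genes = 10L))
    out <- run_pipeline(cfg, tempfile(sprintf("e2e_%d_", s)),
                        n_iter = 50, network_min_size = 6)
    cand <- out$candidates
    nrow(cand) >= 1 && cand$gene_id[1] == "G_chain"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
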