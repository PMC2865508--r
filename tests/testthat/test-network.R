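test_that("variable-gene ranking follows the ceiling rule and skips constants", {
  set.seed(1)
  expr <- matrix(rnorm(50 * 100), 50, 100,
                 dimnames = list(NULL, sprintf("g%03d", 1:100)))
  expect_length(rank_variable_genes(expr, 0.25), 25)
  expr[, "g001"] <- 5                      # constant gene
  expect_false("g001" %in% rank_variable_genes(expr, 0.25))
  expr7 <- expr[, 1:7]
  expect_length(rank_variable_genes(expr7, 0.25), 2)
  expect_error(rank_variable_genes(expr, 0), "top_frac")
})

test_that("topological overlap matches the formula evaluated by hand", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.3
  a[2, 3] <- a[3, 2] <- 0.2
  tom <- esnpnet:::tom_from_adjacency(a)
  # k = (0.8, 0.7, 0.5); w12 = (0.3*0.2 + 0.5) / (0.7 + 1 - 0.5)
  expect_equal(tom[1, 2], (0.3 * 0.2 + 0.5) / (0.7 + 1 - 0.5))
  expect_equal(tom[1, 3], (0.5 * 0.2 + 0.3) / (0.5 + 1 - 0.3))
  expect_equal(tom[2, 3], (0.5 * 0.3 + 0.2) / (0.5 + 1 - 0.2))
  expect_equal(diag(tom), rep(1, 3))

  # brute-force double-sum oracle on a random instance
  set.seed(2)
  x <- matrix(runif(64, 0, 0.9), 8, 8); x <- (x + t(x)) / 2; diag(x) <- 0
  expect_equal(esnpnet:::tom_from_adjacency(x), tom_brute_force(x),
               tolerance = 1e-12)
  tomx <- esnpnet:::tom_from_adjacency(x)
  expect_true(all(tomx >= 0 & tomx <= 1))
  expect_equal(tomx, t(tomx))
})

test_that("planted two-module designs are recovered and noise stays unassigned", {
  cfg <- sim_config(seed = 33, n_snps = 40, n_samples = 200, n_genes = 160,
                    cis_effect = 0, esnp_frac = 0,
                    module_spec = list(sizes = c(50L, 50L),
                                       loadings = c(0.9, 0.9),
                                       causal_effect = 0))
  pan <- simulate_genotypes(cfg)
  expr <- simulate_expression(pan$geno, pan$snps, pan$genes, cfg)
  net <- coexpression_modules(expr)
  truth <- attr(expr, "modules")
  lab_t <- truth$module[match(net$modules$gene_id, truth$gene_id)]
  lab_t[is.na(lab_t)] <- 0L
  expect_equal(sort(unique(net$modules$module[net$modules$module > 0])), 1:2)
  expect_gte(rand_index(lab_t, net$modules$module), 0.95)
  # noise genes (60 of them) stay unassigned
  noise <- setdiff(colnames(expr), truth$gene_id)
  expect_gt(mean(net$modules$module[match(noise, net$modules$gene_id)] == 0),
            0.95)
})

test_that("independent noise forms no module", {
  none <- vapply(1:20, function(s) {
    set.seed(400 + s)
    expr <- matrix(rnorm(150 * 70), 150, 70,
                   dimnames = list(NULL, sprintf("g%02d", 1:70)))
    net <- coexpression_modules(expr, min_size = 30)
    all(net$modules$module == 0)
  }, TRUE)
  expect_gte(mean(none), 0.95)
})

test_that("constant genes are reported by name", {
  set.seed(3)
  expr <- matrix(rnorm(100 * 80), 100, 80,
                 dimnames = list(NULL, sprintf("g%02d", 1:80)))
  expr[, "g07"] <- 1
  expect_error(coexpression_modules(expr), "g07")
})

test_that("module labels are invariant to gene input order", {
  cfg <- sim_config(seed = 34, n_snps = 40, n_samples = 150, n_genes = 120,
                    cis_effect = 0, esnp_frac = 0,
                    module_spec = list(sizes = c(40L, 40L),
                                       loadings = c(0.9, 0.9),
                                       causal_effect = 0))
  pan <- simulate_genotypes(cfg)
  expr <- simulate_expression(pan$geno, pan$snps, pan$genes, cfg)
  net1 <- coexpression_modules(expr, min_size = 20)
  set.seed(4)
  perm <- sample(ncol(expr))
  net2 <- coexpression_modules(expr[, perm], min_size = 20)
  m1 <- setNames(net1$modules$module, net1$modules$gene_id)
  m2 <- setNames(net2$modules$module, net2$modules$gene_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("module eigengene has the documented variance and orientation behaviour", {
  set.seed(5)
  base <- rnorm(100)
  rank1 <- sapply(1:10, function(i) base * (0.5 + i / 10))
  colnames(rank1) <- sprintf("g%02d", 1:10)
  eg <- module_eigengene(rank1, colnames(rank1))
  expect_equal(eg$var_explained, 1.0)
  expect_gt(cor(eg$scores, rowMeans(scale(rank1))), 0)

  noise <- matrix(rnorm(200 * 50), 200, 50,
                  dimnames = list(NULL, sprintf("n%02d", 1:50)))
  eg_n <- module_eigengene(noise, colnames(noise))
  expect_lt(eg_n$var_explained, 0.15)
  # sign invariance
  eg_neg <- module_eigengene(-noise, colnames(noise))
  expect_equal(eg_neg$var_explained, eg_n$var_explained)
  # PC1 explains at least an average gene's share
  expect_gte(eg_n$var_explained, 1 / 50)
  expect_error(module_eigengene(noise, "n01"), "module size")
})

test_that("eigengene-trait correlation recovers a planted loading", {
  ok <- vapply(1:50, function(s) {
    set.seed(600 + s)
    n <- 500
    f <- rnorm(n)
    expr <- sapply(1:30, function(i) 0.9 * f + rnorm(n))
    colnames(expr) <- sprintf("g%02d", 1:30)
    trait <- 0.7 * f + sqrt(1 - 0.49) * rnorm(n)
    eg <- module_eigengene(expr, colnames(expr))
    ct <- module_trait_cor(eg, data.frame(t1 = trait))
    abs(ct$r[1] - 0.7) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  set.seed(6)
  eg_s <- rnorm(50)
  ct <- module_trait_cor(eg_s, data.frame(same = eg_s, flip = -eg_s))
  expect_equal(ct$r, c(1, -1))
  expect_error(module_trait_cor(eg_s, data.frame(k = rep(1, 50))), "constant")
})
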