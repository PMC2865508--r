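# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small panel + expression + gwas used by several files.
small_study <- function() fixture("small_study", {
  cfg <- sim_config(seed = 42, n_snps = 400, n_samples = 200, n_genes = 100)
  panel <- simulate_genotypes(cfg)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, cfg)
  gwas <- simulate_gwas(panel$geno, panel$snps, cfg,
                        driver_snps = attr(expr, "drivers")$snp_id)
  list(cfg = cfg, panel = panel, expr = expr, gwas = gwas)
})

# Plain Rand index from two labelings (pair-counting contingency formula).
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  s_ij <- sum(choose(tab, 2))
  s_i <- sum(choose(rowSums(tab), 2))
  s_j <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  (npairs + 2 * s_ij - s_i - s_j) / npairs
}

# Independent brute-force Kruskal-Wallis: midranks, tie correction,
# textbook formula.  Kept deliberately separate from the package code path.
kw_brute_force <- function(g, y) {
  n <- length(y)
  r <- rank(y)
  groups <- split(r, g)
  H <- 12 / (n * (n + 1)) * sum(vapply(groups, function(rg)
    sum(rg)^2 / length(rg), 0)) - 3 * (n + 1)
  ties <- table(y)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / C
  list(H = H, p = pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Brute-force topological overlap by explicit double sum.
tom_brute_force <- function(a) {
  diag(a) <- 0
  p <- nrow(a)
  k <- colSums(a)
  w <- matrix(1, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (i != j) {
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    w[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# Hypergeometric upper tail by explicit enumeration with choose().
hyper_upper_brute <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
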