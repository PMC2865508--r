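# Synthetic-data generators: LD-blocked genotypes, expression with cis
# effects and module structure, an independent GWAS cohort, and an F2 cross.

# P(X > z, Y > z) for standard bivariate normal with correlation rho,
# by 1-D quadrature of the conditional tail.
bvn_upper_quadrant <- function(z, rho) {
  if (rho <= 0) {
    if (rho == 0) return(pnorm(z, lower.tail = FALSE)^2)
    stop("negative latent correlation not supported")
  }
  rho <- min(rho, 0.9999999)
  f <- function(x) dnorm(x) * pnorm((rho * x - z) / sqrt(1 - rho^2))
  stats::integrate(f, z, Inf, rel.tol = 1e-10)$value
}

# Phi coefficient between two alleles obtained by thresholding equally
# correlated latent normals at frequency maf.
allele_phi <- function(rho, maf) {
  z <- qnorm(1 - maf)
  (bvn_upper_quadrant(z, rho) - maf^2) / (maf * (1 - maf))
}

# Latent correlation needed so the thresholded allele (hence genotype)
# correlation equals target_r.  Thresholding attenuates correlation, so the
# latent value is solved from the tetrachoric relation rather than used raw.
calibrate_latent_rho <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  if (target_r >= 1) stop("within-block correlation must be < 1")
  uniroot(function(rho) allele_phi(rho, maf) - target_r,
          lower = 1e-9, upper = 1 - 1e-9, tol = 1e-9)$root
}

# Genotypes for one block: two latent-Gaussian haplotypes per sample,
# equicorrelated at latent_rho, thresholded at the block MAF.
sim_block_genotypes <- function(n, m, maf, latent_rho) {
  z <- qnorm(1 - maf)
  g <- matrix(0L, n, m)
  for (h in 1:2) {
    common <- rnorm(n)
    lat <- sqrt(latent_rho) * common +
      sqrt(1 - latent_rho) * matrix(rnorm(n * m), n, m)
    g <- g + (lat > z)
  }
  g
}

#' Simulate an LD-blocked SNP panel with gene annotations
#'
#' SNPs are laid along chromosomes at fixed spacing and partitioned into LD
#' blocks; within a block all pairs share one MAF and a genotype correlation
#' calibrated to `within_block_r` via a latent-Gaussian haplotype copula
#' (the latent correlation is solved from the tetrachoric relation so the
#' realized allele-count correlation, not the latent one, hits the target).
#' Genes tile the proximal 70% of each chromosome, leaving a distal
#' gene-free region so the panel contains both gene-proximal and distal
#' SNPs for location-matched resampling.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (samples x SNPs matrix of 0/1/2 allele counts),
#'   `snps` (data.frame: snp_id, chrom, pos, maf, block, latent_rho) and
#'   `genes` (data.frame: gene_id, chrom, start, stop; 1-based inclusive).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(derive_seed(config$seed, "genotypes"), {
    n <- config$n_samples
    S <- config$n_snps
    per_chrom <- rep(S %/% config$n_chromosomes, config$n_chromosomes)
    extra <- S - sum(per_chrom)
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

    snp_rows <- list(); geno_cols <- list(); block_id <- 0L
    for (ch in seq_len(config$n_chromosomes)) {
      k <- per_chrom[ch]
      sizes <- rep(config$block_sizes, length.out = ceiling(k / min(config$block_sizes)) *
                     length(config$block_sizes))
      sizes <- sizes[cumsum(sizes) - sizes < k]
      if (sum(sizes) > k) sizes[length(sizes)] <- k - sum(sizes[-length(sizes)])
      pos <- seq_len(k) * config$snp_spacing_bp
      off <- 0L
      for (b in seq_along(sizes)) {
        m <- sizes[b]; block_id <- block_id + 1L
        maf <- runif(1, config$maf_range[1] + 1e-6, config$maf_range[2] - 1e-6)
        rho <- calibrate_latent_rho(config$within_block_r, maf)
        geno_cols[[block_id]] <- sim_block_genotypes(n, m, maf, rho)
        snp_rows[[block_id]] <- data.frame(
          chrom = sprintf("chr%d", ch), pos = pos[off + seq_len(m)],
          maf = maf, block = block_id, latent_rho = rho)
        off <- off + m
      }
    }
    snps <- do.call(rbind, snp_rows)
    snps <- data.frame(snp_id = sprintf("rs%05d", seq_len(nrow(snps))), snps,
                       stringsAsFactors = FALSE)
    geno <- do.call(cbind, geno_cols)
    dimnames(geno) <- list(sprintf("S%04d", seq_len(n)), snps$snp_id)

    # gene annotations: tile the proximal 70% of each chromosome
    per_chrom_genes <- rep(config$n_genes %/% config$n_chromosomes,
                           config$n_chromosomes)
    eg <- config$n_genes - sum(per_chrom_genes)
    if (eg > 0) per_chrom_genes[seq_len(eg)] <- per_chrom_genes[seq_len(eg)] + 1L
    gene_rows <- list()
    for (ch in seq_len(config$n_chromosomes)) {
      chrom_len <- per_chrom[ch] * config$snp_spacing_bp
      region <- floor(0.7 * chrom_len)
      ng <- per_chrom_genes[ch]
      starts <- floor(seq(1, max(1, region - config$gene_length_bp),
                          length.out = ng))
      gene_rows[[ch]] <- data.frame(
        chrom = sprintf("chr%d", ch), start = starts,
        stop = starts + config$gene_length_bp - 1L, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, gene_rows)
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(nrow(genes))),
                        genes, stringsAsFactors = FALSE)
    rownames(snps) <- NULL; rownames(genes) <- NULL
    list(geno = geno, snps = snps, genes = genes)
  })
}

#' Simulate expression with cis-eQTL effects and module architecture
#'
#' Each designated cis pair contributes `cis_effect` x allele count; each
#' module gene additionally loads on a module factor driven by one
#' module-driving SNP (`factor = causal_effect * scaled driver genotype +
#' N(0,1)`); every gene carries unit-variance Gaussian noise.  Truth
#' annotations (designated pairs, module membership, driver SNPs, factor
#' scores) are attached as attributes for downstream calibration checks.
#'
#' @param geno,snps,genes panel as produced by [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param pairs optional data.frame (snp_id, gene_id) of designated cis
#'   pairs; defaults to the nearest SNP of a random `esnp_frac` subset of
#'   genes.  Pairs violating the 1 Mb cis rule are rejected.
#' @return samples x genes expression matrix with truth attributes
#'   `esnp_pairs`, `modules`, `drivers`, `factors`.
#' @export
simulate_expression <- function(geno, snps, genes, config, pairs = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(geno) == config$n_samples)
  with_local_seed(derive_seed(config$seed, "expression"), {
    n <- nrow(geno); G <- nrow(genes)
    if (is.null(pairs)) {
      n_esnp <- round(config$esnp_frac * G)
      target_genes <- if (n_esnp > 0) sort(sample(genes$gene_id, n_esnp)) else character()
      pairs <- do.call(rbind, lapply(target_genes, function(g) {
        gi <- genes[genes$gene_id == g, ]
        cand <- snps[snps$chrom == gi$chrom, ]
        d <- pmax(0, pmax(gi$start - cand$pos, cand$pos - gi$stop))
        data.frame(snp_id = cand$snp_id[which.min(d)], gene_id = g,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(pairs)) pairs <- data.frame(snp_id = character(),
                                              gene_id = character())
    }
    for (i in seq_len(nrow(pairs))) {
      if (classify_cis(snps[snps$snp_id == pairs$snp_id[i], ],
                       genes[genes$gene_id == pairs$gene_id[i], ]) != "cis")
        stop(sprintf("designated pair %s-%s violates the 1 Mb cis rule",
                     pairs$snp_id[i], pairs$gene_id[i]), call. = FALSE)
    }

    expr <- matrix(rnorm(n * G), n, G,
                   dimnames = list(rownames(geno), genes$gene_id))
    if (config$cis_effect != 0 && nrow(pairs) > 0)
      for (i in seq_len(nrow(pairs)))
        expr[, pairs$gene_id[i]] <- expr[, pairs$gene_id[i]] +
          config$cis_effect * geno[, pairs$snp_id[i]]

    ms <- config$module_spec
    modules <- data.frame(gene_id = character(), module = integer())
    drivers <- data.frame(module = integer(), snp_id = character())
    factors <- NULL
    if (!is.null(ms) && length(ms$sizes) > 0) {
      free <- setdiff(genes$gene_id, pairs$gene_id)
      if (length(free) < sum(ms$sizes)) free <- genes$gene_id
      picked <- sample(free, sum(ms$sizes))
      modules <- data.frame(gene_id = picked,
                            module = rep(seq_along(ms$sizes), ms$sizes),
                            stringsAsFactors = FALSE)
      # each module is driven by a cis variant of its first member (the
      # module's "regulator" gene), so the driver SNP is itself a cis eSNP
      regulators <- vapply(seq_along(ms$sizes), function(m)
        modules$gene_id[modules$module == m][1], "")
      drv <- vapply(regulators, function(g) {
        gi <- genes[genes$gene_id == g, ]
        cand <- snps[snps$chrom == gi$chrom, ]
        d <- pmax(0, pmax(gi$start - cand$pos, cand$pos - gi$stop))
        cand$snp_id[which.min(d)]
      }, "")
      drivers <- data.frame(module = seq_along(ms$sizes), snp_id = unname(drv),
                            regulator = regulators, stringsAsFactors = FALSE)
      for (m in seq_along(ms$sizes)) {
        if (config$cis_effect != 0 && !regulators[m] %in% pairs$gene_id) {
          expr[, regulators[m]] <- expr[, regulators[m]] +
            config$cis_effect * geno[, drv[m]]
          pairs <- rbind(pairs, data.frame(snp_id = unname(drv[m]),
                                           gene_id = regulators[m],
                                           stringsAsFactors = FALSE))
        }
      }
      factors <- sapply(seq_along(ms$sizes), function(m) {
        g <- geno[, drv[m]]
        gz <- if (sd(g) > 0) as.numeric(scale(g)) else rep(0, n)
        ms$causal_effect * gz + rnorm(n)
      })
      colnames(factors) <- sprintf("M%d", seq_along(ms$sizes))
      for (m in seq_along(ms$sizes)) {
        gm <- modules$gene_id[modules$module == m]
        expr[, gm] <- expr[, gm] + ms$loadings[m] * factors[, m]
      }
    }
    structure(expr, esnp_pairs = pairs, modules = modules,
              drivers = drivers, factors = factors)
  })
}

# Vectorized 2x3 genotype contingency chi-square (no continuity correction);
# columns with an empty genotype class lose the corresponding df.
genotype_chisq_p <- function(geno, case) {
  n <- nrow(geno); nc <- sum(case); nn <- n - nc
  counts_case <- sapply(0:2, function(g) colSums(geno[case, , drop = FALSE] == g))
  counts_ctrl <- sapply(0:2, function(g) colSums(geno[!case, , drop = FALSE] == g))
  tot <- counts_case + counts_ctrl                     # SNPs x 3
  chi2 <- rep(0, ncol(geno)); df <- rowSums(tot > 0) - 1L
  for (g in 1:3) {
    e_case <- nc * tot[, g] / n; e_ctrl <- nn * tot[, g] / n
    ok <- tot[, g] > 0
    chi2[ok] <- chi2[ok] + (counts_case[ok, g] - e_case[ok])^2 / e_case[ok] +
      (counts_ctrl[ok, g] - e_ctrl[ok])^2 / e_ctrl[ok]
  }
  p <- rep(1, ncol(geno))
  ok <- df >= 1
  p[ok] <- pchisq(chi2[ok], df[ok], lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Simulate GWAS summary statistics on an independent cohort
#'
#' A new cohort is generated from the same LD-block copula parameters as the
#' panel (mirroring the design in which the GWAS cohorts are distinct from
#' the expression cohorts).  Disease liability is a unit-variance Gaussian
#' plus `liability_effect` times each module factor (reconstructed from the
#' module-driving SNP genotypes in the new cohort); cases are individuals
#' above the liability quantile implied by `prevalence`.  Each SNP is tested
#' by a 2x3 genotype chi-square (or the 1 df trend test).
#'
#' @param geno_pool panel genotype matrix (used only for identifier checks).
#' @param snps panel SNP table from [simulate_genotypes()] (block and
#'   latent_rho columns required to regenerate the cohort).
#' @param config a [sim_config()].
#' @param driver_snps character vector of module-driving SNP ids (take from
#'   `attr(expr, "drivers")$snp_id`); NULL simulates a fully null GWAS.
#' @return data.frame (snp_id, chrom, pos, p) with attribute `study`.
#' @export
simulate_gwas <- function(geno_pool, snps, config, driver_snps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("block", "latent_rho") %in% names(snps)))
    stop("snps must carry 'block' and 'latent_rho' columns from simulate_genotypes()",
         call. = FALSE)
  if (!is.null(geno_pool) && !identical(colnames(geno_pool), snps$snp_id))
    stop("geno_pool columns do not match the SNP table", call. = FALSE)
  gs <- config$gwas_spec
  if (!is.finite(gs$liability_effect)) stop("liability effect must be finite")
  with_local_seed(derive_seed(config$seed, "gwas"), {
    n <- gs$n_gwas_samples
    cohort <- matrix(0L, n, nrow(snps))
    for (b in unique(snps$block)) {
      idx <- which(snps$block == b)
      cohort[, idx] <- sim_block_genotypes(n, length(idx), snps$maf[idx[1]],
                                           snps$latent_rho[idx[1]])
    }
    colnames(cohort) <- snps$snp_id
    liab <- rnorm(n)
    if (!is.null(driver_snps) && length(driver_snps) > 0 &&
        gs$liability_effect != 0) {
      ce <- config$module_spec$causal_effect %||% 0
      for (d in driver_snps) {
        g <- cohort[, d]
        gz <- if (sd(g) > 0) as.numeric(scale(g)) else rep(0, n)
        liab <- liab + gs$liability_effect * (ce * gz + rnorm(n))
      }
    }
    case <- liab > qnorm(1 - gs$prevalence) * sd(liab)
    if (sum(case) == 0 || sum(case) == n)
      stop("liability threshold produced zero cases or zero controls",
           call. = FALSE)
    p <- if (identical(gs$test, "trend")) {
      vapply(seq_len(ncol(cohort)), function(j) {
        tab <- vapply(0:2, function(g) sum(case & cohort[, j] == g), 0)
        nt <- vapply(0:2, function(g) sum(cohort[, j] == g), 0)
        keep <- nt > 0
        if (sum(keep) < 2) return(1)
        suppressWarnings(stats::prop.trend.test(tab[keep], nt[keep],
                                                score = (0:2)[keep])$p.value)
      }, 0)
    } else genotype_chisq_p(cohort, case)
    structure(data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                         pos = snps$pos, p = p, stringsAsFactors = FALSE),
              study = "synthetic")
  })
}

#' Simulate an F2 intercross with a locus-expression-trait chain
#'
#' Marker genotypes follow Mendelian 1:2:1 expectations with recombination
#' between adjacent markers per Haldane's map function.  One marker (the
#' middle of chromosome 1) drives a chain gene and a clinical trait under
#' the configured dependency structure: causal (L -> G -> T), reactive
#' (L -> T -> G) or independent (L -> G, L -> T with independent noises).
#' Clinical traits `insulin` (the chain trait), `glucose` (negatively
#' correlated) and `islet_count` (positively correlated) mirror the trait
#' correlation signs seen in diabetes crosses.
#'
#' @param config a [sim_config()]; see `cross_spec`.
#' @return object of class `cross_data`: list with `geno` (individuals x
#'   markers, codes 0/1/2 = AA/AB/BB), `map` (marker, chrom, cM), `expr`,
#'   `traits`, and `truth` (locus, model, chain gene).
#' @export
simulate_f2_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$cross_spec
  if (cs$spacing_cM < 0) stop("marker spacing must be non-negative", call. = FALSE)
  if (!cs$model %in% c("causal", "reactive", "independent"))
    stop("cross model must be causal, reactive or independent", call. = FALSE)
  with_local_seed(derive_seed(config$seed, "cross"), {
    n <- cs$n_f2
    cm <- if (cs$spacing_cM == 0) c(0, 0)
          else seq(0, cs$chrom_length_cM, by = cs$spacing_cM)
    maps <- list(); genos <- list()
    for (ch in seq_len(cs$n_chromosomes)) {
      M <- length(cm)
      g <- matrix(0L, n, M)
      for (h in 1:2) {
        hap <- matrix(0L, n, M)
        hap[, 1] <- rbinom(n, 1, 0.5)
        if (M > 1) for (k in 2:M) {
          r <- 0.5 * (1 - exp(-2 * (cm[k] - cm[k - 1]) / 100))
          swap <- rbinom(n, 1, r)
          hap[, k] <- ifelse(swap == 1, 1L - hap[, k - 1], hap[, k - 1])
        }
        g <- g + hap
      }
      colnames(g) <- sprintf("c%d.m%02d", ch, seq_len(M))
      genos[[ch]] <- g
      maps[[ch]] <- data.frame(marker = colnames(g),
                               chrom = sprintf("chr%d", ch), cM = cm,
                               stringsAsFactors = FALSE)
    }
    geno <- do.call(cbind, genos)
    rownames(geno) <- sprintf("F2_%04d", seq_len(n))
    map <- do.call(rbind, maps); rownames(map) <- NULL

    locus <- maps[[1]]$marker[ceiling(nrow(maps[[1]]) / 2)]
    a <- geno[, locus] - 1
    if (cs$model == "causal") {
      G <- cs$b_LG * a + cs$sd_G * rnorm(n)
      T_ <- cs$b_GT * G + cs$sd_T * rnorm(n)
    } else if (cs$model == "reactive") {
      T_ <- cs$b_LG * a + cs$sd_T * rnorm(n)
      G <- cs$b_GT * T_ + cs$sd_G * rnorm(n)
    } else {
      G <- cs$b_LG * a + cs$sd_G * rnorm(n)
      T_ <- cs$b_GT * a + cs$sd_T * rnorm(n)
    }
    nng <- cs$n_noise_genes %||% 0L
    expr <- cbind(G_chain = G,
                  matrix(rnorm(n * nng), n, nng,
                         dimnames = list(NULL, if (nng > 0)
                           sprintf("G_noise%03d", seq_len(nng)))))
    rownames(expr) <- rownames(geno)
    tz <- as.numeric(scale(T_))
    traits <- data.frame(insulin = T_,
                         glucose = -0.6 * tz + 0.8 * rnorm(n),
                         islet_count = 0.7 * tz + sqrt(1 - 0.49) * rnorm(n),
                         row.names = rownames(geno))
    structure(list(geno = geno, map = map, expr = expr, traits = traits,
                   truth = list(locus = locus, model = cs$model,
                                chain_gene = "G_chain")),
              class = "cross_data")
  })
}

#' @export
print.cross_data <- function(x, ...) {
  cat(sprintf("F2 cross: %d individuals, %d markers on %d chromosomes, %d expression traits\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              ncol(x$expr)))
  cat(sprintf("  chain: %s -> %s -> insulin (%s model)\n",
              x$truth$locus, x$truth$chain_gene, x$truth$model))
  invisible(x)
}
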