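#' Simulation configuration for the synthetic study
#'
#' Bundles every parameter of the synthetic-data generators: an LD-blocked
#' SNP panel, expression with cis effects and a module (factor) architecture,
#' an independent GWAS cohort with a liability-threshold case definition, and
#' an F2 intercross carrying a locus -> expression -> trait causal chain.
#'
#' The defaults define the study conditions used throughout the package's
#' analysis scripts: a panel of LD blocks of 5 SNPs correlated at r = 0.8
#' with MAF above 5%, 300 expression samples, standardized cis effects of 1
#' per allele, two 50-gene co-expression modules with loadings 0.9, a GWAS
#' cohort of 2,000 individuals with prevalence 0.2, and a 554-animal F2
#' cross genotyped at 10 cM spacing (matching the size of the mouse cross
#' that motivates the cross generator).
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param n_samples expression-cohort sample count.
#' @param n_chromosomes number of autosomes to simulate.
#' @param block_sizes integer vector of SNPs per LD block, recycled across
#'   chromosomes until `n_snps` is reached.
#' @param n_snps total SNP count (split evenly across chromosomes).
#' @param within_block_r target pairwise genotype correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range interval within `(0.05, 0.5]` from which block MAFs are
#'   drawn (one MAF per block, strictly inside the interval).
#' @param snp_spacing_bp base-pair spacing between consecutive SNPs.
#' @param n_genes number of annotated genes (tiled over the gene-bearing
#'   portion of each chromosome; the distal 30% of each chromosome is left
#'   gene-free so the panel contains both gene-proximal and distal SNPs).
#' @param gene_length_bp annotated gene length.
#' @param cis_effect standardized expression effect per allele at designated
#'   cis eSNPs.
#' @param esnp_frac fraction of genes designated to carry a cis eSNP.
#' @param module_spec list: `sizes` (gene counts per module), `loadings`
#'   (factor loading per module, in `[0, 1]`), `causal_effect` (effect of the
#'   module-driving SNP on the module factor).  The default plants two
#'   modules of 10% of the genes each (50 genes at the default `n_genes`)
#'   with loadings 0.9 driven at effect 0.5; `NULL` disables modules.
#' @param gwas_spec list: `n_gwas_samples`, `liability_effect` (liability
#'   effect of each module factor), `prevalence` (liability-threshold case
#'   fraction), `test` ("genotype" 2 df chi-square or "trend" 1 df).
#' @param cross_spec list: `n_f2`, `spacing_cM`, `chrom_length_cM`,
#'   `n_chromosomes`, `model` (one of "causal", "reactive", "independent"),
#'   `b_LG`, `b_GT`, `sd_G`, `sd_T`, `n_noise_genes`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 300L,
                       n_chromosomes = 4L,
                       block_sizes = 5L,
                       n_snps = 2000L,
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       snp_spacing_bp = 50000L,
                       n_genes = 500L,
                       gene_length_bp = 10000L,
                       cis_effect = 1.0,
                       esnp_frac = 0.3,
                       module_spec = NULL,
                       gwas_spec = list(n_gwas_samples = 2000L,
                                        liability_effect = 0.3,
                                        prevalence = 0.2,
                                        test = "genotype"),
                       cross_spec = list(n_f2 = 554L,
                                         spacing_cM = 10,
                                         chrom_length_cM = 100,
                                         n_chromosomes = 4L,
                                         model = "causal",
                                         b_LG = 0.7, b_GT = 0.7,
                                         sd_G = 1, sd_T = 1,
                                         n_noise_genes = 50L)) {
  stop_if_not_scalar_count(n_samples, "n_samples")
  stop_if_not_scalar_count(n_chromosomes, "n_chromosomes")
  stop_if_not_scalar_count(n_snps, "n_snps")
  stop_if_not_scalar_count(n_genes, "n_genes")
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1)
    stop("'within_block_r' must lie in [0, 1)", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] < 0.05 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2])
    stop("'maf_range' must be an increasing interval within (0.05, 0.5]",
         call. = FALSE)
  if (any(block_sizes < 1) || any(block_sizes != floor(block_sizes)))
    stop("'block_sizes' must be positive integers", call. = FALSE)
  if (missing(module_spec)) {
    # default architecture: two modules of 10% of the genes each
    sz <- max(2L, as.integer(floor(0.1 * n_genes)))
    module_spec <- list(sizes = c(sz, sz), loadings = c(0.9, 0.9),
                        causal_effect = 0.5)
  }
  if (!is.null(module_spec)) {
    if (any(module_spec$loadings < 0 | module_spec$loadings > 1))
      stop("module loadings must lie in [0, 1]", call. = FALSE)
    if (length(module_spec$loadings) != length(module_spec$sizes))
      stop("module_spec$loadings and $sizes must have equal length",
           call. = FALSE)
    if (sum(module_spec$sizes) > n_genes)
      stop("module sizes exceed n_genes", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_chromosomes = as.integer(n_chromosomes),
                 block_sizes = as.integer(block_sizes),
                 n_snps = as.integer(n_snps),
                 within_block_r = within_block_r, maf_range = maf_range,
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 n_genes = as.integer(n_genes),
                 gene_length_bp = as.integer(gene_length_bp),
                 cis_effect = cis_effect, esnp_frac = esnp_frac,
                 module_spec = module_spec, gwas_spec = gwas_spec,
                 cross_spec = cross_spec),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  panel : %d SNPs on %d chromosomes, blocks of %s, r=%.2f, MAF in (%.2f, %.2f]\n",
              x$n_snps, x$n_chromosomes,
              paste(unique(x$block_sizes), collapse = "/"),
              x$within_block_r, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  cohort: %d samples, %d genes, cis effect %.2f, %d modules\n",
              x$n_samples, x$n_genes, x$cis_effect,
              length(x$module_spec$sizes %||% integer())))
  cat(sprintf("  gwas  : %d samples, liability effect %.2f, prevalence %.2f\n",
              x$gwas_spec$n_gwas_samples, x$gwas_spec$liability_effect,
              x$gwas_spec$prevalence))
  cat(sprintf("  cross : %d F2, %g cM spacing, model %s\n",
              x$cross_spec$n_f2, x$cross_spec$spacing_cM, x$cross_spec$model))
  invisible(x)
}
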