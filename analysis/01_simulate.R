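#!/usr/bin/env Rscript
# Build the synthetic study that stands in for the human GGE cohorts, the
# T2D GWAS summary statistics and the F2 intercross: an LD-blocked SNP
# panel (2,000 SNPs, blocks of 5 at r = 0.8, MAF > 5%), 300 expression
# samples with planted cis eSNPs and two co-expression modules whose
# drivers feed disease liability in an independent 2,000-sample GWAS
# cohort, and a 554-animal cross carrying a locus -> expression -> insulin
# causal chain.

library(esnpnet)

cfg <- sim_config(seed = 1)
print(cfg)

objs <- simulate_study(cfg, "results/study")

message(sprintf("panel    : %d SNPs in %d LD blocks on %d chromosomes",
                nrow(objs$panel$snps), max(objs$panel$snps$block),
                cfg$n_chromosomes))
message(sprintf("expression: %d samples x %d genes; %d designated cis pairs; %d modules",
                nrow(objs$expr), ncol(objs$expr),
                nrow(attr(objs$expr, "esnp_pairs")),
                nrow(attr(objs$expr, "drivers"))))
message(sprintf("GWAS     : %d SNPs scored; %.1f%% with p < 0.05",
                nrow(objs$gwas), 100 * mean(objs$gwas$p < 0.05)))
print(objs$cross)
message("study written under results/study/")
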