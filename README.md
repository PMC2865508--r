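# esnpnet

Expression-associated SNPs (eSNPs) — variants that associate with the
expression of a gene, detected in genetics-of-gene-expression cohorts —
are a functionally annotated slice of the genome.  `esnpnet` implements a
complete, tested pipeline for asking whether an eSNP set is enriched for
association with a disease (here, type 2 diabetes) in GWAS summary
statistics, and for sharpening that enrichment by filtering the eSNPs
through a co-expression network and a causally supported subnetwork, down
to a short list of candidate genes supported in both a mouse cross and a
human cohort.

It is written for statistical geneticists and systems-biology analysts who
want the full chain — eQTL mapping, LD handling, matched resampling,
network construction, causal inference in an F2 cross, and gene-set
statistics — as composable R functions that run at desk scale on
synthetic data emulating the real study designs.

## The statistics at the core

**Matched-resampling SNP-set enrichment.**  For a focal SNP set *S* and a
GWAS threshold α (default 0.05), the observed statistic is the fraction of
*S* with GWAS p < α.  The null is the same fraction over random sets drawn
from the genotyped pool and matched to *S* exactly on: MAF bin
((5–10], (10–20], (20–30], (30–40], (40–50] percent), gene proximity
(cis-mode SNPs are matched by SNPs within 1 Mb of a gene), and LD
multiplicity (k focal SNPs sharing one LD group are matched by k SNPs from
a single pool LD group).  For LD-expanded sets (all panel SNPs with
|r| > 0.89 to a member), random sets are additionally rejection-sampled to
within ±10% of the expanded focal size.  Reported are the empirical
add-one p-value (1 + #{null ≥ obs})/(n_iter + 1), the plain strict
proportion, the fold `obs / null_mean`, Z, and a one-sided normal-tail
approximation at Z.

**eQTL mapping.**  Kruskal–Wallis association per SNP–gene pair, cis
defined as within 1 Mb of transcription start/stop (boundary inclusive),
an empirically determined FDR < 10% from whole-matrix permutations of the
expression labels, and LD-pruned reporting (one SNP per correlated group
per gene at |r| > 0.89).

**Co-expression network.**  Top 25% most-variable genes; unsigned
adjacency |cor|^β (β = 6); topological overlap
ω_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij); average-linkage
clustering of 1 − ω with a static cut; module eigengenes (PC1 of z-scored
module expression) correlated with clinical traits.

**Causal inference at QTL.**  Marker LOD scans ((n/2)·log10(RSS0/RSS1)),
forward stepwise multi-QTL selection, a bivariate-Gaussian pleiotropy LRT
(χ², 4 df), and AIC selection among causal (L→G→T), reactive (L→T→G) and
independent (L→G, L→T) linear-Gaussian models.  A three-criteria filter
returns module genes with (1) a cis-eQTL inside the linkage interval,
(2) causal support for a clinical trait, and (3) a human-ortholog cis
eSNP associated with disease.

**Gene-set statistics.**  Hypergeometric over-representation with fold
`k / (nK/N)` against an explicit universe, two-group t-test knockout
signatures with Storey q-values (single-λ π₀), and sex-adjusted phenotype
comparisons with per-sex percent changes.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 1; 2,000 SNPs, 300 samples, 500 genes, a 554-animal cross):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_esnp_mapping.R
Rscript analysis/04_enrichment.R   # after 03_network.R
```

The mapping step prints

```
tested 19760 cis SNP-gene pairs; 821 pass FDR < 10% after LD pruning
p-value threshold t* = 4.82e-03; 694 unique eSNPs for 186 genes
designated pairs recovered exactly: 152 / 152 (100%)
```

— all planted cis effects are recovered at the 10% empirical FDR.  The
enrichment step then prints the filtering cascade:

```
all eSNPs                n= 694  obs  4.47%  null  4.29% ( 3.20- 5.38)  fold 1.04  Z  0.32  p 0.424
expanded eSNPs           n= 696  obs  4.45%  null  4.25% ( 3.16- 5.34)  fold 1.05  Z  0.37  p 0.334
module eSNPs vs all      n=  23  obs 43.48%  null  5.85% (-3.49-15.20)  fold 7.43  Z  7.89  p 0.0001
```

The full eSNP set is barely enriched (most eSNPs are irrelevant to the
simulated disease), while restricting to eSNPs of module genes — whose
driver variants feed disease liability — concentrates the signal into a
large, highly significant fold increase.  That is the pipeline's central
behaviour: network filtering turns a diffuse signal into a sharp one.
Finally `analysis/06_candidates.R` applies the three-criteria filter and
recovers the single planted end-to-end gene:

```
1 candidate gene(s):
  G_chain -> human G0253: cis-eQTL LOD 30.5, causal for insulin, best eSNP rs01006 at P = 1.82e-05
```

A single orchestrated run of every stage is also available as
`run_pipeline(sim_config(seed = 1), "out_dir")`, with cached, resumable,
byte-reproducible stage outputs.

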