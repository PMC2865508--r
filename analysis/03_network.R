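#!/usr/bin/env Rscript
# Reconstruct the weighted co-expression network from the most variable
# quarter of the genes, cut modules from the topological overlap
# dendrogram, and summarize each module by its eigengene (first principal
# component of the z-scored module expression).

library(esnpnet)

bundle <- load_study("results/study/study.yaml")
expr <- bundle$expr

top <- rank_variable_genes(expr, top_frac = 0.25)
message(sprintf("network input: top 25%% most variable genes = %d of %d",
                length(top), ncol(expr)))

net <- coexpression_modules(expr[, top], beta = 6, cut_height = 0.998,
                            min_size = 30)
sizes <- table(net$modules$module[net$modules$module > 0])
message(sprintf("detected %d modules (sizes: %s); %d genes unassigned",
                length(sizes), paste(sizes, collapse = ", "),
                sum(net$modules$module == 0)))

truth <- read_table_tsv("results/study/truth_modules.tsv")
for (m in sort(unique(net$modules$module[net$modules$module > 0]))) {
  genes_m <- net$modules$gene_id[net$modules$module == m]
  eg <- module_eigengene(expr, genes_m)
  overlap <- max(table(truth$module[match(genes_m, truth$gene_id)]))
  message(sprintf("module %d: %d genes, PC1 explains %.1f%% of variation, best planted overlap %d",
                  m, length(genes_m), 100 * eg$var_explained, overlap))
}

write_table_tsv(net$modules, "results/modules.tsv")
message("wrote results/modules.tsv")
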