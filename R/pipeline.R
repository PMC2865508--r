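# Stage-oriented orchestration of the full analysis on one study bundle:
# esnp -> expand -> enrich -> network -> causal -> candidates -> genesets.
# Every stage is resumable from its on-disk outputs and all randomness
# derives from the single top-level seed.

stage_done <- function(dir, files) all(file.exists(file.path(dir, files)))

#' Run the full eSNP filtering pipeline on a (synthetic) study
#'
#' Executes the stages in order, writing each stage's tables under
#' `out_dir` and skipping stages whose outputs already exist, so an
#' interrupted run resumes from its intermediates.  A provenance JSON
#' records the seed and parameters; identical config + seed yields
#' byte-identical outputs.
#'
#' @param config a [sim_config()] describing the synthetic study.
#' @param out_dir output directory.
#' @param n_iter enrichment iterations (default 1000 at desk scale).
#' @param n_perm eQTL permutations (default 10).
#' @param fdr_target empirical FDR bound for eSNP detection.
#' @param alpha GWAS significance threshold.
#' @param network_top_frac fraction of most-variable genes entering the
#'   network (default 0.25).
#' @param network_min_size minimum module size for the network stage.
#' @param force rerun every stage even if outputs exist.
#' @return invisibly, a list of the principal stage results.
#' @export
run_pipeline <- function(config, out_dir, n_iter = 1000L, n_perm = 10L,
                         fdr_target = 0.10, alpha = 0.05,
                         network_top_frac = 0.25, network_min_size = 30L,
                         force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- file.path(out_dir, "inputs")
  results <- list()

  run_stage <- function(name, outputs, fun) {
    if (!force && stage_done(out_dir, outputs)) {
      message(sprintf("[%s] skipping (cached outputs present)", name))
      return(invisible(NULL))
    }
    message(sprintf("[%s] running", name))
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate ------------------------------------------------------------
  run_stage("simulate", file.path("inputs", "study.yaml"), function() {
    simulate_study(config, inputs)
  })
  panel_geno <- read_genotypes_tsv(file.path(inputs, "genotypes.tsv"))
  snps <- read_table_tsv(file.path(inputs, "snps.tsv"))
  genes <- read_table_tsv(file.path(inputs, "genes.tsv"))
  expr <- read_matrix_tsv(file.path(inputs, "expression.tsv"))
  gwas <- read_table_tsv(file.path(inputs, "gwas.tsv"))
  drivers <- read_table_tsv(file.path(inputs, "truth_drivers.tsv"))

  # --- esnp ----------------------------------------------------------------
  run_stage("esnp", "esnps.tsv", function() {
    es <- map_esnps(panel_geno, snps, expr, genes,
                    fdr_target = fdr_target, n_perm = n_perm,
                    seed = derive_seed(config$seed, "stage_esnp"))
    message(sprintf("[esnp] %d associations pass FDR < %.0f%% (of %d tested pairs)",
                    nrow(es), 100 * fdr_target, attr(es, "n_tested")))
    write_table_tsv(es, file.path(out_dir, "esnps.tsv"))
  })
  esnps <- read_table_tsv(file.path(out_dir, "esnps.tsv"))

  # --- expand --------------------------------------------------------------
  run_stage("expand", "expanded_esnps.tsv", function() {
    ex <- expand_set(unique(esnps$snp_id), panel_geno, snps)
    message(sprintf("[expand] %d core -> %d expanded eSNPs",
                    length(ex$core_set), length(ex$expanded_set)))
    write_table_tsv(data.frame(snp_id = ex$expanded_set,
                               core = ex$expanded_set %in% ex$core_set),
                    file.path(out_dir, "expanded_esnps.tsv"))
  })
  expanded <- read_table_tsv(file.path(out_dir, "expanded_esnps.tsv"))

  # --- network -------------------------------------------------------------
  run_stage("network", c("modules.tsv", "eigengenes.tsv"), function() {
    top <- rank_variable_genes(expr, network_top_frac)
    net <- coexpression_modules(expr[, top], min_size = network_min_size)
    write_table_tsv(net$modules, file.path(out_dir, "modules.tsv"))
    egs <- lapply(setdiff(sort(unique(net$modules$module)), 0L), function(m) {
      eg <- module_eigengene(expr, net$modules$gene_id[net$modules$module == m])
      data.frame(module = m, sample = names(eg$scores), score = eg$scores,
                 var_explained = eg$var_explained, stringsAsFactors = FALSE)
    })
    eg_df <- if (length(egs)) do.call(rbind, egs) else
      data.frame(module = integer(), sample = character(),
                 score = numeric(), var_explained = numeric())
    write_table_tsv(eg_df, file.path(out_dir, "eigengenes.tsv"))
    message(sprintf("[network] %d modules among %d most-variable genes",
                    length(egs), length(top)))
  })
  modules <- read_table_tsv(file.path(out_dir, "modules.tsv"))

  # --- enrich --------------------------------------------------------------
  run_stage("enrich", "enrichment.tsv", function() {
    keys <- match_keys(snps, genes, panel_geno)
    modes <- setNames(esnps$mode, esnps$snp_id)
    rows <- list()
    add <- function(label, res) {
      rows[[label]] <<- data.frame(
        set = label, n_snps = res$n_snps,
        observed_pct = 100 * res$observed_prop,
        null_mean_pct = 100 * res$null_mean,
        ci_lo_pct = 100 * res$ci95[1], ci_hi_pct = 100 * res$ci95[2],
        fold = res$fold, z = res$z, p_empirical = res$p_empirical,
        p_approx = res$p_approx, stringsAsFactors = FALSE)
    }
    core_ids <- unique(esnps$snp_id)
    seed_e <- derive_seed(config$seed, "stage_enrich")
    add("all_esnps", enrichment_test(core_ids, keys, gwas, n_iter = n_iter,
                                     alpha = alpha, seed = seed_e,
                                     focal_modes = modes))
    add("expanded_esnps",
        enrichment_test(core_ids, keys, gwas, n_iter = n_iter, alpha = alpha,
                        expand = list(geno = panel_geno), seed = seed_e + 1L,
                        focal_modes = modes))
    mod_genes <- modules$gene_id[modules$module > 0]
    mod_ids <- unique(esnps$snp_id[esnps$gene_id %in% mod_genes])
    if (length(mod_ids) >= 5) {
      cmp <- compare_sets(mod_ids, keys[keys$snp_id %in% core_ids, ], gwas,
                          n_iter = n_iter, alpha = alpha, seed = seed_e + 2L,
                          focal_modes = modes)
      add("module_esnps_vs_all", cmp$result)
    }
    write_table_tsv(do.call(rbind, rows), file.path(out_dir, "enrichment.tsv"))
  })

  # --- causal --------------------------------------------------------------
  cross <- simulate_f2_cross(config)
  run_stage("causal", c("lod_insulin.tsv", "causal_calls.tsv"), function() {
    lods <- qtl_scan(cross, "insulin")
    write_table_tsv(lods, file.path(out_dir, "lod_insulin.tsv"))
    L <- cross$geno[, cross$truth$locus]
    calls <- lapply(colnames(cross$expr), function(g) {
      cc <- causal_model_select(L, cross$expr[, g], cross$traits$insulin)
      data.frame(gene_id = g, trait = "insulin", locus = cross$truth$locus,
                 model = cc$model, margin = cc$margin,
                 stringsAsFactors = FALSE)
    })
    write_table_tsv(do.call(rbind, calls), file.path(out_dir, "causal_calls.tsv"))
    message(sprintf("[causal] insulin LOD peak %.1f at %s",
                    max(lods$lod), lods$marker[which.max(lods$lod)]))
  })
  causal_calls <- read_table_tsv(file.path(out_dir, "causal_calls.tsv"))

  # --- candidates ----------------------------------------------------------
  run_stage("candidates", "candidates.tsv", function() {
    # mouse cis-eQTL evidence: LOD of each cross expression trait at the
    # marker nearest its annotated position (chain gene sits at the locus)
    locus_row <- cross$map[cross$map$marker == cross$truth$locus, ]
    eq <- do.call(rbind, lapply(colnames(cross$expr), function(g) {
      lod <- lod_from_fit(cross$expr[, g], {
        cd <- genotype_codes(cross$geno[, cross$truth$locus])
        cbind(cd$a, cd$d)
      })
      data.frame(gene_id = g, chrom = locus_row$chrom,
                 pos = if (g == cross$truth$chain_gene) locus_row$cM
                       else -1e6,   # noise genes annotated off-interval
                 lod = lod, stringsAsFactors = FALSE)
    }))
    # orthologs: the chain gene maps to module 1's regulator in the human
    # panel; noise genes map round-robin to other human genes
    reg <- drivers$regulator[1]
    other_mouse <- setdiff(colnames(cross$expr), cross$truth$chain_gene)
    other_human <- setdiff(genes$gene_id, reg)[seq_along(other_mouse)]
    orth <- data.frame(mouse_id = c(cross$truth$chain_gene, other_mouse),
                       human_id = c(reg, other_human),
                       stringsAsFactors = FALSE)
    cand <- candidate_filter(
      module_genes = colnames(cross$expr),
      mouse_cis_eqtl = eq, mouse_causal = causal_calls,
      interval = list(chrom = locus_row$chrom,
                      start = locus_row$cM - 20, stop = locus_row$cM + 20),
      human_esnps = esnps, gwas = gwas, orthologs = orth,
      p_threshold = alpha)
    write_table_tsv(cand, file.path(out_dir, "candidates.tsv"))
    message(sprintf("[candidates] %d gene(s) satisfy all three criteria",
                    nrow(cand)))
  })

  # --- genesets ------------------------------------------------------------
  run_stage("genesets", "geneset_enrichment.tsv", function() {
    truth_mod <- read_table_tsv(file.path(inputs, "truth_modules.tsv"))
    sets <- split(truth_mod$gene_id, paste0("planted_module_",
                                            truth_mod$module))
    detected <- modules$gene_id[modules$module > 0]
    tab <- if (length(detected) && length(sets))
      geneset_enrichment_table(detected, sets, universe_size = ncol(expr))
    else data.frame()
    write_table_tsv(tab, file.path(out_dir, "geneset_enrichment.tsv"))
  })

  jsonlite::write_json(
    list(seed = config$seed,
         parameters = list(n_iter = n_iter, n_perm = n_perm,
                           fdr_target = fdr_target, alpha = alpha,
                           network_top_frac = network_top_frac),
         package_version = as.character(utils::packageVersion("esnpnet"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(esnps = esnps, expanded = expanded, modules = modules,
                 causal_calls = causal_calls,
                 candidates = read_table_tsv(file.path(out_dir, "candidates.tsv")),
                 enrichment = read_table_tsv(file.path(out_dir, "enrichment.tsv"))))
}
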