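# cis/trans eQTL detection: Kruskal-Wallis association, 1 Mb cis window,
# permutation-based empirical FDR, LD-pruned reporting.

#' Kruskal-Wallis association between a genotype and an expression trait
#'
#' Wraps [stats::kruskal.test()] on genotype groups (0/1/2 allele counts),
#' dropping missing entries pairwise.  A constant expression vector is an
#' uninformative but valid input and returns H = 0, p = 1 (the tie-corrected
#' statistic is 0/0 there, resolved to no evidence against the null).
#'
#' @param genotypes integer vector with values in {0,1,2} (NA allowed).
#' @param expression numeric vector of the same length.
#' @return list with `H` (statistic) and `p` (chi-square p, groups-1 df).
#' @export
kruskal_wallis <- function(genotypes, expression) {
  if (length(genotypes) != length(expression))
    stop("genotype and expression vectors differ in length", call. = FALSE)
  keep <- !is.na(genotypes) & !is.na(expression)
  g <- genotypes[keep]; y <- expression[keep]
  if (length(unique(g)) < 2)
    stop("fewer than two genotype groups present; SNP untestable", call. = FALSE)
  if (length(unique(y)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(y, factor(g))
  list(H = unname(kt$statistic), p = kt$p.value)
}

# Vectorized tie-corrected Kruskal-Wallis of one genotype vector against a
# pre-ranked expression matrix (samples x genes).  `tie_corr` is the per-gene
# tie correction 1 - sum(t^3 - t)/(n^3 - n); exact agreement with
# stats::kruskal.test is asserted in the test suite.
kw_matrix <- function(g, rank_mat, tie_corr) {
  n <- length(g)
  grp <- factor(g, levels = sort(unique(g)))
  ng <- tabulate(grp)
  rs <- rowsum(rank_mat, grp, reorder = TRUE)        # groups x genes
  H <- 12 / (n * (n + 1)) * colSums(rs^2 / ng) - 3 * (n + 1)
  H <- H / tie_corr
  df <- nlevels(grp) - 1L
  p <- pchisq(H, df, lower.tail = FALSE)
  p[tie_corr == 0] <- 1                               # constant traits
  p
}

tie_correction <- function(y) {
  n <- length(y)
  tt <- table(y)
  1 - sum(tt^3 - tt) / (n^3 - n)
}

#' Classify a SNP-gene pair as cis or trans
#'
#' cis iff the SNP lies on the gene's chromosome within `window` base pairs
#' of the transcription start or stop (distance <= window counts as cis;
#' the boundary is inclusive).  Coordinates are 1-based inclusive.
#'
#' @param snp one-row data.frame with `chrom`, `pos`.
#' @param gene one-row data.frame with `chrom`, `start`, `stop`.
#' @param window cis window in bp (default 1 Mb).
#' @return "cis" or "trans".
#' @export
classify_cis <- function(snp, gene, window = 1e6) {
  if (nrow(snp) != 1 || nrow(gene) != 1) stop("expected one SNP and one gene")
  if (snp$chrom != gene$chrom) return("trans")
  if (snp$pos >= gene$start - window && snp$pos <= gene$stop + window) "cis"
  else "trans"
}

# cis pair list: for each gene, indices of SNPs within the window.
cis_pairs <- function(snps, genes, window) {
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    res[[i]] <- which(snps$chrom == gi$chrom &
                        snps$pos >= gi$start - window &
                        snps$pos <= gi$stop + window)
  }
  names(res) <- genes$gene_id
  res
}

#' Map eSNPs by Kruskal-Wallis with permutation-based empirical FDR
#'
#' cis tests are restricted to SNPs within `window` of each gene; trans
#' tests (optional) cover all remaining SNP x gene pairs up to
#' `max_trans_pairs`.  The null is built by shuffling expression sample
#' labels `n_perm` times and re-testing exactly the same pairs, so cis
#' permutations stay within the cis windows.  For a threshold t,
#' `FDR(t) = (mean permuted count at t) / (observed count at t)`; the
#' largest observed p value t* with FDR(t*) < `fdr_target` defines
#' `fdr_pass`.  Among passing SNPs for one gene that are mutually correlated
#' above `prune_r`, only the smallest-p SNP is reported (ties broken by
#' lexicographically smallest snp_id).
#'
#' @param geno samples x SNPs allele-count matrix.
#' @param snps SNP table (snp_id, chrom, pos, maf).
#' @param expr samples x genes expression matrix (same row order as geno).
#' @param genes gene annotation table (gene_id, chrom, start, stop).
#' @param window cis window in bp.
#' @param fdr_target empirical FDR bound (default 0.10).
#' @param n_perm number of whole-matrix label permutations (default 10).
#' @param seed RNG seed for the permutations.
#' @param trans also test trans pairs (default FALSE).
#' @param max_trans_pairs cap on the number of trans pairs tested.
#' @param tissue label recorded in the output.
#' @param keep_all return every tested pair with its `fdr_pass` flag instead
#'   of only the pruned significant associations.
#' @return data.frame (snp_id, gene_id, mode, kw_p, fdr_pass, tissue) with
#'   attributes `threshold` (t*), `n_tested`, `n_perm`.
#' @export
map_esnps <- function(geno, snps, expr, genes, window = 1e6,
                      fdr_target = 0.10, n_perm = 10L, seed = 1L,
                      trans = FALSE, max_trans_pairs = 50000L,
                      tissue = "synthetic", keep_all = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!identical(rownames(geno), rownames(expr)))
    stop("sample identifiers of geno and expr are not aligned", call. = FALSE)
  n <- nrow(geno)
  cp <- cis_pairs(snps, genes, window)
  pair_snp <- unlist(lapply(cp, function(ix) ix), use.names = FALSE)
  pair_gene <- rep(seq_along(cp), lengths(cp))
  mode <- rep("cis", length(pair_snp))

  if (trans) {
    all_pairs <- expand.grid(snp = seq_len(nrow(snps)),
                             gene = seq_len(nrow(genes)))
    key_cis <- paste(pair_snp, pair_gene)
    tp <- all_pairs[!(paste(all_pairs$snp, all_pairs$gene) %in% key_cis), ]
    if (nrow(tp) > max_trans_pairs) {
      tp <- with_local_seed(derive_seed(seed, "trans_cap"),
                            tp[sample(nrow(tp), max_trans_pairs), ])
    }
    pair_snp <- c(pair_snp, tp$snp)
    pair_gene <- c(pair_gene, tp$gene)
    mode <- c(mode, rep("trans", nrow(tp)))
  }
  if (length(pair_snp) == 0) {
    warning("no testable SNP-gene pairs")
    return(structure(data.frame(snp_id = character(), gene_id = character(),
                                mode = character(), kw_p = numeric(),
                                fdr_pass = logical(), tissue = character()),
                     threshold = NA_real_, n_tested = 0L, n_perm = n_perm))
  }

  rank_mat <- apply(expr, 2, rank)
  tie_corr <- apply(expr, 2, tie_correction)
  has_na <- anyNA(geno)

  eval_pairs <- function(rmat) {
    p <- numeric(length(pair_snp))
    for (j in unique(pair_snp)) {
      sel <- which(pair_snp == j)
      gcols <- pair_gene[sel]
      g <- geno[, j]
      if (has_na && anyNA(g)) {
        for (k in seq_along(sel)) {
          y <- rmat[, gcols[k]]
          keep <- !is.na(g)
          yk <- y[keep]
          p[sel[k]] <- kw_matrix(g[keep], matrix(rank(yk)), tie_correction(yk))
        }
      } else if (length(unique(g)) < 2) {
        p[sel] <- NA_real_
      } else {
        p[sel] <- kw_matrix(g, rmat[, gcols, drop = FALSE], tie_corr[gcols])
      }
    }
    p
  }

  p_obs <- eval_pairs(rank_mat)
  perm_ps <- with_local_seed(derive_seed(seed, "esnp_perm"), {
    lapply(seq_len(n_perm), function(b) eval_pairs(rank_mat[sample(n), , drop = FALSE]))
  })
  testable <- !is.na(p_obs)
  p_all_perm <- sort(unlist(perm_ps)[rep(testable, n_perm)])

  # plug-in FDR over candidate thresholds = observed p values
  cand <- sort(unique(p_obs[testable]))
  obs_cnt <- findInterval(cand, sort(p_obs[testable]))
  null_cnt <- findInterval(cand, p_all_perm) / n_perm
  fdr <- null_cnt / pmax(obs_cnt, 1)
  ok <- which(fdr < fdr_target)
  threshold <- if (length(ok)) max(cand[ok]) else -Inf
  fdr_pass <- testable & p_obs <= threshold

  out <- data.frame(snp_id = snps$snp_id[pair_snp],
                    gene_id = genes$gene_id[pair_gene],
                    mode = mode, kw_p = p_obs, fdr_pass = fdr_pass,
                    tissue = tissue, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$kw_p, out$snp_id), ]

  # LD pruning: one SNP per correlated group per gene among passing SNPs
  keep_row <- rep(TRUE, nrow(out))
  for (g in unique(out$gene_id[out$fdr_pass])) {
    rows <- which(out$gene_id == g & out$fdr_pass)
    if (length(rows) < 2) next
    sub <- geno[, out$snp_id[rows], drop = FALSE]
    r <- suppressWarnings(abs(cor(sub, use = "pairwise.complete.obs")))
    r[is.na(r)] <- 0
    comp <- threshold_components(r > 0.89)
    for (cmp in unique(comp)) {
      members <- rows[comp == cmp]
      if (length(members) < 2) next
      best <- members[order(out$kw_p[members], out$snp_id[members])][1]
      keep_row[setdiff(members, best)] <- FALSE
    }
  }
  reported <- if (keep_all) out[keep_row | !out$fdr_pass, ]
              else out[out$fdr_pass & keep_row, ]
  rownames(reported) <- NULL
  structure(reported, threshold = threshold,
            n_tested = sum(testable), n_perm = n_perm)
}

# Connected components of a logical adjacency matrix via union-find.
threshold_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j && adj[i, j]) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}
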