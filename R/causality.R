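# F2-cross genetics: single-marker LOD scans, forward stepwise multi-QTL
# selection, a bivariate pleiotropy LRT, likelihood-based causal/reactive/
# independent model selection, and the three-criteria candidate-gene filter.

# Additive (-1/0/1) and dominance (0/1) codes from 0/1/2 genotypes.
genotype_codes <- function(g) {
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    stop("F2 genotypes must be coded 0/1/2 (AA/AB/BB)", call. = FALSE)
  list(a = g - 1, d = as.numeric(g == 1))
}

lod_from_fit <- function(trait, X) {
  keep <- complete.cases(trait, X)
  y <- trait[keep]; Xk <- X[keep, , drop = FALSE]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  fit <- lm.fit(cbind(1, Xk), y)
  rss1 <- sum(fit$residuals^2)
  (n / 2) * log10(rss0 / rss1)
}

#' Single-marker QTL scan
#'
#' At each marker the trait is regressed on additive plus dominance codes;
#' `LOD = (n/2) log10(RSS0 / RSS1)`, equivalently `-(n/2) log10(1 - R^2)`.
#'
#' @param cross a `cross_data` object (see [simulate_f2_cross()]).
#' @param trait numeric vector over the cross individuals (or the name of a
#'   column of `cross$traits` / `cross$expr`).
#' @return data.frame (marker, chrom, cM, lod) of class `lod_curve`.
#' @export
qtl_scan <- function(cross, trait) {
  stopifnot(inherits(cross, "cross_data"))
  if (is.character(trait) && length(trait) == 1) {
    trait <- if (trait %in% names(cross$traits)) cross$traits[[trait]]
             else cross$expr[, trait]
  }
  if (sd(trait, na.rm = TRUE) == 0) stop("constant trait", call. = FALSE)
  if (sum(complete.cases(trait)) < 30)
    stop("fewer than 30 informative individuals", call. = FALSE)
  lod <- vapply(seq_len(ncol(cross$geno)), function(j) {
    cd <- genotype_codes(cross$geno[, j])
    lod_from_fit(trait, cbind(cd$a, cd$d))
  }, 0)
  structure(data.frame(marker = colnames(cross$geno),
                       chrom = cross$map$chrom, cM = cross$map$cM,
                       lod = pmax(lod, 0), stringsAsFactors = FALSE),
            class = c("lod_curve", "data.frame"))
}

#' Forward stepwise multi-QTL selection
#'
#' Iteratively adds the marker with the largest conditional LOD (LOD of the
#' model with the new marker's additive + dominance codes versus the model
#' with the already-selected markers) while the increment exceeds
#' `lod_threshold`.
#'
#' @inheritParams qtl_scan
#' @param lod_threshold conditional LOD needed to add a marker (default 3).
#' @param max_qtl optional cap on the number of selected markers.
#' @return data.frame (marker, chrom, cM, conditional_lod), possibly empty.
#' @export
forward_stepwise_qtl <- function(cross, trait, lod_threshold = 3.0,
                                 max_qtl = Inf) {
  stopifnot(inherits(cross, "cross_data"))
  if (is.character(trait) && length(trait) == 1) {
    trait <- if (trait %in% names(cross$traits)) cross$traits[[trait]]
             else cross$expr[, trait]
  }
  if (sd(trait, na.rm = TRUE) == 0) stop("constant trait", call. = FALSE)
  keep <- complete.cases(trait, cross$geno)
  y <- trait[keep]; n <- length(y)
  codes <- lapply(seq_len(ncol(cross$geno)), function(j) {
    cd <- genotype_codes(cross$geno[keep, j]); cbind(cd$a, cd$d)
  })
  selected <- integer(0); cond_lod <- numeric(0)
  X <- matrix(1, n, 1)
  rss_cur <- sum((y - mean(y))^2)
  while (length(selected) < max_qtl) {
    cand <- setdiff(seq_along(codes), selected)
    inc <- vapply(cand, function(j) {
      rss_new <- sum(lm.fit(cbind(X, codes[[j]]), y)$residuals^2)
      (n / 2) * log10(rss_cur / rss_new)
    }, 0)
    best <- which.max(inc)
    if (!length(best) || inc[best] <= lod_threshold) break
    j <- cand[best]
    selected <- c(selected, j); cond_lod <- c(cond_lod, inc[best])
    X <- cbind(X, codes[[j]])
    rss_cur <- sum(lm.fit(X, y)$residuals^2)
  }
  data.frame(marker = colnames(cross$geno)[selected],
             chrom = cross$map$chrom[selected],
             cM = cross$map$cM[selected],
             conditional_lod = cond_lod, stringsAsFactors = FALSE)
}

#' Bivariate pleiotropy test at a marker
#'
#' Likelihood-ratio test of a bivariate Gaussian model in which the marker
#' (additive + dominance) affects both traits against the model in which it
#' affects neither; the statistic is `n log(det(S0) / det(S1))` with S the
#' maximum-likelihood residual covariance, referred to a chi-square with
#' 4 degrees of freedom (two codes x two traits).
#'
#' @param marker_geno 0/1/2 genotype vector.
#' @param trait1,trait2 numeric trait vectors.
#' @return list with `lrt`, `df`, `p`.
#' @export
pleiotropy_test <- function(marker_geno, trait1, trait2) {
  keep <- complete.cases(marker_geno, trait1, trait2)
  if (sum(keep) < 30) stop("fewer than 30 jointly complete individuals",
                           call. = FALSE)
  y <- cbind(trait1[keep], trait2[keep])
  if (isTRUE(all.equal(y[, 1], y[, 2])))
    stop("identical traits: residual covariance is singular", call. = FALSE)
  cd <- genotype_codes(marker_geno[keep])
  n <- nrow(y)
  r0 <- sweep(y, 2, colMeans(y))
  r1 <- lm.fit(cbind(1, cd$a, cd$d), y)$residuals
  s0 <- crossprod(r0) / n; s1 <- crossprod(r1) / n
  lrt <- n * log(det(s0) / det(s1))
  list(lrt = lrt, df = 4, p = pchisq(lrt, 4, lower.tail = FALSE))
}

#' Causal / reactive / independent model selection for a (L, G, T) triple
#'
#' Compares three linear-Gaussian dependency structures among a locus L
#' (0/1/2 genotypes, coded additive + dominance), an expression trait G and
#' a clinical trait T:
#' causal `P(G|L) P(T|G)`, reactive `P(T|L) P(G|T)`, independent
#' `P(G|L) P(T|L)` (the marginal `P(L)` is common to all three and drops
#' out).  Each conditional is a Gaussian linear model; models are scored by
#' AIC and the winner is the minimum, with the margin to the runner-up
#' reported.  "Supported as causal" conventionally requires winner = causal
#' with margin >= 2.
#'
#' @param L 0/1/2 genotype vector.
#' @param G expression vector.
#' @param T_ clinical trait vector.
#' @return list of class `causal_call`: `model`, `aic` (named vector),
#'   `margin` (AIC gap winner to runner-up), `logLik`.
#' @export
causal_model_select <- function(L, G, T_) {
  keep <- complete.cases(L, G, T_)
  L <- L[keep]; G <- G[keep]; T_ <- T_[keep]
  if (sd(G) == 0 || sd(T_) == 0)
    stop("degenerate variance in G or T", call. = FALSE)
  cd <- genotype_codes(L)
  a <- cd$a; d <- cd$d
  aic2 <- function(fit) as.numeric(AIC(fit))
  ll <- function(fit) as.numeric(logLik(fit))
  m_GL <- lm(G ~ a + d); m_TG <- lm(T_ ~ G)
  m_TL <- lm(T_ ~ a + d); m_GT <- lm(G ~ T_)
  aic <- c(causal = aic2(m_GL) + aic2(m_TG),
           reactive = aic2(m_TL) + aic2(m_GT),
           independent = aic2(m_GL) + aic2(m_TL))
  lls <- c(causal = ll(m_GL) + ll(m_TG),
           reactive = ll(m_TL) + ll(m_GT),
           independent = ll(m_GL) + ll(m_TL))
  ord <- order(aic)
  structure(list(model = names(aic)[ord[1]], aic = aic,
                 margin = aic[ord[2]] - aic[ord[1]], logLik = lls),
            class = "causal_call")
}

#' @export
print.causal_call <- function(x, ...) {
  cat(sprintf("Model selection: %s (AIC margin %.2f)\n", x$model, x$margin))
  print(round(x$aic, 2))
  invisible(x)
}

#' Three-criteria candidate-gene filter
#'
#' Returns module genes that (1) lie inside the configured linkage interval
#' and show a cis-eQTL with LOD at or above `lod_threshold` in the cross,
#' (2) are supported as causal for at least one clinical trait (winner =
#' causal with AIC margin at or above `aic_margin`), and (3) have a human
#' ortholog with a cis eSNP (FDR-passing) whose GWAS p-value is below
#' `p_threshold`.  Candidates are ordered by ascending best human GWAS p.
#'
#' @param module_genes character vector of (mouse) module gene ids.
#' @param mouse_cis_eqtl data.frame (gene_id, chrom, pos, lod): the gene's
#'   location and its best cis-eQTL LOD in the cross.
#' @param mouse_causal data.frame (gene_id, trait, model, margin) of causal
#'   calls in the cross.
#' @param interval list(chrom, start, stop): the linkage interval.
#' @param human_esnps data.frame (snp_id, gene_id, mode, fdr_pass) with
#'   human gene ids.
#' @param gwas data.frame (snp_id, p).
#' @param orthologs data.frame (mouse_id, human_id).
#' @param p_threshold GWAS significance threshold (default 0.05).
#' @param lod_threshold cis-eQTL LOD threshold (default 3).
#' @param aic_margin causal-support AIC margin (default 2).
#' @return data.frame (gene_id, human_id, lod, causal_traits, best_snp,
#'   p_t2d), possibly empty, ordered by ascending p_t2d.
#' @export
candidate_filter <- function(module_genes, mouse_cis_eqtl, mouse_causal,
                             interval, human_esnps, gwas, orthologs,
                             p_threshold = 0.05, lod_threshold = 3,
                             aic_margin = 2) {
  uncovered <- setdiff(module_genes, orthologs$mouse_id)
  if (length(uncovered))
    message(sprintf("%d module genes without ortholog mapping skipped",
                    length(uncovered)))
  genes <- intersect(module_genes, orthologs$mouse_id)

  out <- list()
  for (g in genes) {
    eq <- mouse_cis_eqtl[mouse_cis_eqtl$gene_id == g, , drop = FALSE]
    crit1 <- nrow(eq) > 0 && any(eq$chrom == interval$chrom &
                                   eq$pos >= interval$start &
                                   eq$pos <= interval$stop &
                                   eq$lod >= lod_threshold)
    if (!crit1) next
    cz <- mouse_causal[mouse_causal$gene_id == g &
                         mouse_causal$model == "causal" &
                         mouse_causal$margin >= aic_margin, , drop = FALSE]
    if (nrow(cz) == 0) next
    hid <- orthologs$human_id[orthologs$mouse_id == g]
    es <- human_esnps[human_esnps$gene_id %in% hid &
                        human_esnps$mode == "cis" &
                        human_esnps$fdr_pass, , drop = FALSE]
    if (nrow(es) == 0) next
    p <- gwas$p[match(es$snp_id, gwas$snp_id)]
    hit <- which(!is.na(p) & p < p_threshold)
    if (!length(hit)) next
    best <- hit[which.min(p[hit])]
    out[[g]] <- data.frame(gene_id = g, human_id = hid[1],
                           lod = max(eq$lod),
                           causal_traits = paste(sort(unique(cz$trait)),
                                                 collapse = ";"),
                           best_snp = es$snp_id[best], p_t2d = p[best],
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(gene_id = character(), human_id = character(),
                         lod = numeric(), causal_traits = character(),
                         best_snp = character(), p_t2d = numeric())
  res <- res[order(res$p_t2d, res$gene_id), ]
  rownames(res) <- NULL
  res
}
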