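# Weighted co-expression network: variance-ranked gene selection,
# soft-thresholded adjacency, topological overlap, static-cut module
# detection, module eigengenes, and module-trait correlations.

#' Select the most variable genes
#'
#' Genes are ranked by the sample variance of their expression (the natural
#' spread measure on a log-ratio scale) and the top `ceiling(top_frac * G)`
#' are returned; ties are broken by gene id.
#'
#' @param expr samples x genes matrix.
#' @param top_frac fraction to keep, in `(0, 1]` (default 0.25).
#' @return character vector of selected gene ids.
#' @export
rank_variable_genes <- function(expr, top_frac = 0.25) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must lie in (0, 1]",
                                          call. = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 genes", call. = FALSE)
  v <- apply(expr, 2, var)
  ord <- order(-v, colnames(expr))
  colnames(expr)[ord[seq_len(ceiling(top_frac * ncol(expr)))]]
}

# Topological overlap of a soft-thresholded adjacency (zero diagonal).
tom_from_adjacency <- function(a) {
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Build a weighted co-expression network and cut modules
#'
#' Adjacency is `|cor(i, j)|^beta` (unsigned; a signed variant keeps the
#' correlation sign gate `cor > 0`).  The topological overlap
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` is
#' clustered by average-linkage on `1 - w`; the tree is cut statically at
#' `cut_height` and clusters smaller than `min_size` are relabeled 0
#' (unassigned).  Module labels are deterministic: decreasing size, ties by
#' smallest member gene id, so they are invariant to gene input order.
#'
#' @param expr samples x genes matrix (no missing values).
#' @param beta soft-threshold exponent (default 6).
#' @param cut_height static cut height on the `1 - TOM` dendrogram
#'   (default 0.998, tuned for unsigned beta = 6 networks where unrelated
#'   genes sit within ~1e-3 of dissimilarity 1 while co-regulated genes
#'   join well below it).
#' @param min_size minimum module size (default 30).
#' @param signed use a signed network (negative correlations get adjacency
#'   0) instead of the unsigned default.
#' @return list with `tom` (genes x genes matrix in `[0, 1]`, unit
#'   diagonal) and `modules` (data.frame gene_id, module; 0 = unassigned),
#'   plus `parameters`.
#' @export
coexpression_modules <- function(expr, beta = 6, cut_height = 0.998,
                                 min_size = 30, signed = FALSE) {
  if (anyNA(expr)) stop("expression matrix contains missing values",
                        call. = FALSE)
  if (ncol(expr) < 2 * min_size)
    stop("need at least 2 * min_size genes", call. = FALSE)
  sds <- apply(expr, 2, sd)
  if (any(sds == 0))
    stop(sprintf("constant gene(s): %s",
                 paste(colnames(expr)[sds == 0], collapse = ", ")),
         call. = FALSE)
  cc <- cor(expr)
  a <- if (signed) (pmax(cc, 0))^beta else abs(cc)^beta
  tom <- tom_from_adjacency(a)
  hc <- hclust(as.dist(1 - tom), method = "average")
  lab <- cutree(hc, h = cut_height)
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= min_size]
  lab[!(lab %in% as.integer(keep))] <- 0L
  # deterministic relabeling: by decreasing size, ties by smallest gene id
  mods <- setdiff(unique(lab), 0L)
  if (length(mods)) {
    info <- data.frame(old = mods,
                       size = vapply(mods, function(m) sum(lab == m), 0L),
                       first = vapply(mods, function(m)
                         min(colnames(expr)[lab == m]), ""))
    info <- info[order(-info$size, info$first), ]
    lab <- match(lab, info$old, nomatch = 0L)
  }
  list(tom = tom,
       modules = data.frame(gene_id = colnames(expr), module = unname(lab),
                            stringsAsFactors = FALSE),
       parameters = list(beta = beta, cut_height = cut_height,
                         min_size = min_size, signed = signed))
}

#' Choose a soft-threshold exponent by scale-free model fit
#'
#' Returns the smallest candidate `beta` whose degree distribution gives a
#' log-log linear model fit with R squared at least `rsq_target`, or the
#' candidate with the best fit if none reaches the target.
#'
#' @param expr samples x genes matrix.
#' @param candidates candidate exponents.
#' @param rsq_target target model fit (default 0.8).
#' @param n_breaks histogram bins for the degree distribution.
#' @return list with `beta` and `fit` (R squared per candidate).
#' @export
pick_soft_threshold <- function(expr, candidates = c(1:10, 12, 14, 16),
                                rsq_target = 0.8, n_breaks = 10) {
  cc <- abs(cor(expr))
  fits <- vapply(candidates, function(b) {
    k <- colSums(cc^b) - 1
    cuts <- cut(k, breaks = n_breaks)
    dk <- tapply(k, cuts, mean)
    pk <- as.numeric(table(cuts)) / length(k)
    keep <- pk > 0 & !is.na(dk) & dk > 0
    if (sum(keep) < 3) return(NA_real_)
    summary(lm(log10(pk[keep]) ~ log10(dk[keep])))$r.squared
  }, 0)
  hit <- which(!is.na(fits) & fits >= rsq_target)
  beta <- if (length(hit)) candidates[hit[1]] else candidates[which.max(fits)]
  list(beta = beta, fit = data.frame(beta = candidates, rsq = fits))
}

#' Module eigengene: first principal component of a module's expression
#'
#' Computed on per-gene z-scored expression; `var_explained` is the leading
#' eigenvalue over the total variance.  The sign is fixed so the eigengene
#' correlates positively with the module's mean expression profile.
#'
#' @param expr samples x genes matrix.
#' @param module_genes character vector of member gene ids (>= 2).
#' @return list of class `eigengene`: `scores` (unit-norm, per sample),
#'   `var_explained`, `module_genes`.
#' @export
module_eigengene <- function(expr, module_genes) {
  if (length(module_genes) < 2) stop("module size must be >= 2", call. = FALSE)
  x <- expr[, module_genes, drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  xs <- scale(x)
  sv <- svd(xs)
  scores <- sv$u[, 1]
  if (cor(scores, rowMeans(xs)) < 0) scores <- -scores
  structure(list(scores = setNames(scores, rownames(expr)),
                 var_explained = sv$d[1]^2 / sum(sv$d^2),
                 module_genes = module_genes),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("Module eigengene over %d genes: PC1 explains %.1f%% of expression variation\n",
              length(x$module_genes), 100 * x$var_explained))
  invisible(x)
}

#' Correlate a module eigengene with clinical traits
#'
#' Pearson correlation with a two-sided t-distribution p-value per trait.
#'
#' @param eigengene an [module_eigengene()] result (or numeric vector).
#' @param traits data.frame of traits over the same samples.
#' @return data.frame (trait, r, p, n).
#' @export
module_trait_cor <- function(eigengene, traits) {
  scores <- if (inherits(eigengene, "eigengene")) eigengene$scores else eigengene
  if (length(scores) < 10) stop("need at least 10 paired samples", call. = FALSE)
  out <- lapply(names(traits), function(tr) {
    y <- traits[[tr]]
    if (sd(y, na.rm = TRUE) == 0)
      stop(sprintf("constant trait '%s'", tr), call. = FALSE)
    ct <- cor.test(scores, y)
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(complete.cases(scores, y)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
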