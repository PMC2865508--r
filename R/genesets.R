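# Hypergeometric gene-set over-representation with fold enrichment,
# two-group t-test knockout signatures with Storey q-values, and
# sex-adjusted phenotype comparison with per-sex percent changes.

#' Hypergeometric (Fisher-exact) gene-set enrichment
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` members of a
#' `K`-gene set in a query of `n` genes from a universe of `N`, computed in
#' log space (stable at p near 1e-70).  The expected overlap is `n K / N`
#' and the fold enrichment is `k / expected`.  The universe `N` is a
#' required explicit argument: over-representation results are meaningless
#' without stating the reference set.
#'
#' @param k observed overlap count.
#' @param n query-set size.
#' @param K gene-set size.
#' @param N universe size.
#' @return list of class `geneset_enrichment`: `k`, `n`, `K`, `N`,
#'   `expected`, `fold`, `p`.
#' @export
hypergeom_enrich <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || k < 0)
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N",
         call. = FALSE)
  expected <- n * K / N
  p <- if (k == 0) 1 else
    exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  structure(list(k = k, n = n, K = K, N = N, expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_,
                 p = min(p, 1)),
            class = "geneset_enrichment")
}

#' @export
print.geneset_enrichment <- function(x, ...) {
  cat(sprintf("Overlap %d of query %d vs set %d in universe %d\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  expected %.2f, fold %.2f, p = %.3g\n",
              x$expected, x$fold, x$p))
  invisible(x)
}

#' Enrichment of a query gene list against every set in a GMT collection
#'
#' @param query character vector of gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe_size explicit universe size `N`.
#' @param universe optional character vector; when given, query and sets
#'   are intersected with it and `universe_size` defaults to its length.
#' @return data.frame (set, k, n, K, N, expected, fold, p) sorted by p.
#' @export
geneset_enrichment_table <- function(query, gene_sets, universe_size = NULL,
                                     universe = NULL) {
  if (!is.null(universe)) {
    query <- intersect(query, universe)
    gene_sets <- lapply(gene_sets, intersect, universe)
    universe_size <- universe_size %||% length(universe)
  }
  if (is.null(universe_size))
    stop("universe size must be given explicitly", call. = FALSE)
  rows <- lapply(names(gene_sets), function(s) {
    gs <- unique(gene_sets[[s]])
    h <- hypergeom_enrich(length(intersect(query, gs)), length(unique(query)),
                          length(gs), universe_size)
    data.frame(set = s, k = h$k, n = h$n, K = h$K, N = h$N,
               expected = h$expected, fold = h$fold, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}

#' Storey q-values with a single-lambda pi0 estimate
#'
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))` capped at 1;
#' `q_i = min over t >= p_i of pi0 m t / #\{p <= t\}`, which makes q
#' monotone in p.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @param lambda pi0 tuning parameter (default 0.5).
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
qvalue <- function(p, lambda = 0.5) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  ranks <- rank(p, ties.method = "max")
  for (i in ord) {
    running <- min(running, pi0 * m * p[i] / ranks[i])
    q[i] <- running
  }
  list(q = pmin(q, 1), pi0 = pi0)
}

#' Two-group t-test expression signature with q-value FDR
#'
#' Equal-variance two-sample t-test per gene between knockout and wild-type
#' expression; the signature is the set of genes with `p < alpha`.  Genes
#' with zero variance in both groups are untestable and flagged with p = 1.
#'
#' @param expr_ko,expr_wt samples x genes matrices with identical gene
#'   columns.
#' @param alpha signature significance level (default 0.05).
#' @return data.frame of class `signature_table` (gene, t, p, q, direction,
#'   in_signature, flag) with attributes `pi0` and `realized_fdr_at_alpha`
#'   (the q-value at the largest signature p).
#' @export
ttest_signature <- function(expr_ko, expr_wt, alpha = 0.05) {
  stopifnot(identical(colnames(expr_ko), colnames(expr_wt)))
  if (nrow(expr_ko) < 2 || nrow(expr_wt) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  G <- ncol(expr_ko)
  t_stat <- p <- numeric(G); flag <- logical(G)
  for (j in seq_len(G)) {
    a <- expr_ko[, j]; b <- expr_wt[, j]
    if (sd(a) == 0 && sd(b) == 0) {
      t_stat[j] <- 0; p[j] <- 1; flag[j] <- TRUE
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      t_stat[j] <- unname(tt$statistic); p[j] <- tt$p.value
    }
  }
  qv <- qvalue(p)
  dirn <- ifelse(colMeans(expr_ko) >= colMeans(expr_wt), "up", "down")
  out <- data.frame(gene = colnames(expr_ko), t = t_stat, p = p, q = qv$q,
                    direction = dirn, in_signature = p < alpha & !flag,
                    flag = flag, stringsAsFactors = FALSE)
  rfdr <- if (any(out$in_signature)) max(out$q[out$in_signature]) else NA_real_
  structure(out, pi0 = qv$pi0, realized_fdr_at_alpha = rfdr,
            class = c("signature_table", "data.frame"))
}

#' Percent change of a group mean relative to a reference mean
#'
#' @param mean_group,mean_ref group (e.g. knockout) and reference (e.g.
#'   wild-type) means.
#' @return `100 * (mean_group - mean_ref) / mean_ref`.
#' @export
percent_change <- function(mean_group, mean_ref) {
  100 * (mean_group - mean_ref) / mean_ref
}

#' Sex-adjusted phenotype comparison between genotype groups
#'
#' Per-sex group means, SDs and percent changes, plus a sex-adjusted
#' p-value from the t-test of the genotype coefficient in
#' `trait ~ genotype + sex`.
#'
#' @param values numeric trait vector.
#' @param genotype factor/character with reference level first (e.g.
#'   "wt", "ko"); the first level encountered is taken as reference unless
#'   the vector is a factor.
#' @param sex factor/character of sexes.
#' @return list of class `phenotype_comparison`: `by_sex` (data.frame sex,
#'   n_ref, n_alt, mean_ref, sd_ref, mean_alt, sd_alt, percent_change) and
#'   `adjusted_p`.
#' @export
phenotype_compare <- function(values, genotype, sex) {
  genotype <- if (is.factor(genotype)) genotype else
    factor(genotype, levels = unique(genotype))
  if (nlevels(droplevels(genotype)) != 2)
    stop("exactly two genotype groups required", call. = FALSE)
  ref <- levels(genotype)[1]; alt <- levels(genotype)[2]
  sexes <- unique(as.character(sex))
  rows <- lapply(sexes, function(s) {
    vr <- values[sex == s & genotype == ref]
    va <- values[sex == s & genotype == alt]
    data.frame(sex = s, n_ref = length(vr), n_alt = length(va),
               mean_ref = mean(vr), sd_ref = sd(vr),
               mean_alt = mean(va), sd_alt = sd(va),
               percent_change = if (length(vr) && length(va))
                 percent_change(mean(va), mean(vr)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  fit <- lm(values ~ genotype + sex)
  co <- summary(fit)$coefficients
  row <- grep("^genotype", rownames(co))
  structure(list(by_sex = do.call(rbind, rows),
                 adjusted_p = co[row, "Pr(>|t|)"],
                 reference = ref, alternative = alt),
            class = "phenotype_comparison")
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat(sprintf("Phenotype comparison (%s vs %s), sex-adjusted p = %.3g\n",
              x$alternative, x$reference, x$adjusted_p))
  print(x$by_sex, row.names = FALSE)
  invisible(x)
}
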