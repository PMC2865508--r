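# Matched-resampling SNP-set enrichment against GWAS summary statistics:
# random sets matched on MAF bin, gene proximity (cis/trans), LD
# multiplicity, and (for expanded sets) total size within +/-10%.

#' Fraction of p-values below a threshold
#'
#' @param p_values numeric vector of p-values.
#' @param alpha threshold (strict inequality; default 0.05).
#' @return fraction in `[0, 1]`.
#' @export
proportion_below <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  mean(p_values < alpha)
}

#' Compute matching keys (MAF bin, gene proximity, LD group) for a SNP panel
#'
#' @param snps SNP table (snp_id, chrom, pos, maf).
#' @param genes gene annotation table.
#' @param geno samples x SNPs matrix (for LD groups).
#' @param window gene-proximity window in bp (default 1 Mb).
#' @param r_threshold LD-group correlation threshold (default 0.89).
#' @param ld_window LD-group positional window in bp.
#' @return data.frame (snp_id, maf_bin, proximal, ld_group).
#' @export
match_keys <- function(snps, genes, geno, window = 1e6, r_threshold = 0.89,
                       ld_window = 1e6) {
  prox <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    prox <- prox | (snps$chrom == gi$chrom & snps$pos >= gi$start - window &
                      snps$pos <= gi$stop + window)
  }
  data.frame(snp_id = snps$snp_id, maf_bin = maf_bin(snps$maf),
             proximal = prox,
             ld_group = as.integer(ld_groups(geno, snps, r_threshold, ld_window)),
             stringsAsFactors = FALSE)
}

# Pre-indexed pool for fast repeated matched draws.
build_match_index <- function(pool) {
  bins <- sort(unique(pool$maf_bin))
  bin_all <- lapply(1:5, function(b) pool$snp_id[pool$maf_bin == b])
  bin_prox <- lapply(1:5, function(b) pool$snp_id[pool$maf_bin == b & pool$proximal])
  grp_sizes <- table(pool$ld_group)
  multi <- as.integer(names(grp_sizes)[grp_sizes >= 2])
  groups <- lapply(multi, function(g) {
    rows <- pool[pool$ld_group == g, ]
    list(ids = rows$snp_id, bins = rows$maf_bin, prox = rows$proximal)
  })
  hist_all <- t(vapply(groups, function(g) tabulate(g$bins, 5), numeric(5)))
  hist_prox <- t(vapply(groups, function(g) tabulate(g$bins[g$prox], 5), numeric(5)))
  if (length(groups) == 0) { hist_all <- hist_prox <- matrix(0, 0, 5) }
  list(bin_all = bin_all, bin_prox = bin_prox, groups = groups,
       hist_all = hist_all, hist_prox = hist_prox)
}

# Focal requirements: LD-multiplicity groups (within the focal set) and
# singleton counts per (bin, mode) stratum.
focal_requirements <- function(focal) {
  grp <- split(seq_len(nrow(focal)), focal$ld_group)
  multi <- grp[lengths(grp) >= 2]
  multi <- multi[order(-lengths(multi), vapply(multi, function(i) focal$snp_id[i[1]], ""))]
  groups <- lapply(multi, function(ix)
    list(bins = focal$maf_bin[ix], cis = focal$mode[ix] == "cis"))
  singles_ix <- unlist(grp[lengths(grp) == 1], use.names = FALSE)
  singles <- focal[singles_ix, c("maf_bin", "mode")]
  counts <- as.data.frame(table(maf_bin = factor(singles$maf_bin, 1:5),
                                mode = factor(singles$mode, c("cis", "trans"))),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  counts$maf_bin <- as.integer(as.character(counts$maf_bin))
  list(groups = groups, singles = counts)
}

# Resolve, once per focal/pool pairing, which pool LD groups can match each
# focal LD-multiplicity group (bin histogram dominance, proximity respected).
attach_candidates <- function(req, index) {
  ng <- nrow(index$hist_all)
  req$groups <- lapply(req$groups, function(g) {
    hb <- tabulate(g$bins, 5)
    hc <- tabulate(g$bins[g$cis], 5)
    if (ng == 0) cand <- integer(0)
    else {
      ok_all <- index$hist_all >= matrix(hb, ng, 5, byrow = TRUE)
      ok_prox <- index$hist_prox >= matrix(hc, ng, 5, byrow = TRUE)
      cand <- which(rowSums(ok_all) == 5 & rowSums(ok_prox) == 5)
    }
    if (!length(cand))
      stop(sprintf("no pool LD group can match a focal group with bins {%s}",
                   paste(g$bins, collapse = ",")), call. = FALSE)
    c(g, list(hb = hb, hc = hc, cand = cand))
  })
  req
}

# One matched draw.  Consumes randomness in a documented order: LD groups
# (largest first), then cis singletons by ascending bin, then trans.
draw_matched_core <- function(req, index, max_attempts = 1000) {
  drawn <- character(0)
  for (g in req$groups) {
    hb <- g$hb; hc <- g$hc; cand <- g$cand
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      gg <- index$groups[[if (length(cand) == 1) cand else sample(cand, 1)]]
      pick <- character(0); feasible <- TRUE
      for (b in which(hb > 0)) {
        inb <- gg$ids[gg$bins == b & !(gg$ids %in% c(drawn, pick))]
        prox_b <- gg$ids[gg$bins == b & gg$prox & !(gg$ids %in% c(drawn, pick))]
        ncis <- hc[b]
        if (length(prox_b) < ncis || length(inb) < hb[b]) { feasible <- FALSE; break }
        chosen_cis <- if (ncis > 0) sample(prox_b, ncis) else character(0)
        rest_pool <- setdiff(inb, chosen_cis)
        chosen_rest <- if (hb[b] - ncis > 0) sample(rest_pool, hb[b] - ncis) else character(0)
        pick <- c(pick, chosen_cis, chosen_rest)
      }
      if (feasible) { drawn <- c(drawn, pick); ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("could not satisfy LD multiplicity for a focal group of size %d after %d attempts",
                   length(g$bins), max_attempts), call. = FALSE)
  }
  sg <- req$singles
  for (mode in c("cis", "trans")) {
    rows <- sg[sg$mode == mode, ]
    for (i in seq_len(nrow(rows))) {
      b <- rows$maf_bin[i]; k <- rows$Freq[i]
      pool_b <- if (mode == "cis") index$bin_prox[[b]] else index$bin_all[[b]]
      avail <- pool_b[!(pool_b %in% drawn)]
      if (length(avail) < k)
        stop(sprintf("infeasible stratum: maf_bin=%d mode=%s needs %d SNPs, pool has %d",
                     b, mode, k, length(avail)), call. = FALSE)
      drawn <- c(drawn, if (length(avail) == 1) avail else sample(avail, k))
    }
  }
  drawn
}

#' Draw one random SNP set matched to a focal set
#'
#' The drawn set reproduces the focal set's (MAF bin x cis/trans) stratum
#' histogram exactly; each focal LD group of size k >= 2 is matched by k
#' SNPs from a single pool LD group with a compatible bin composition.
#' Sampling is without replacement within one draw.  cis-mode SNPs are
#' matched by gene-proximal pool SNPs; trans-mode SNPs by any pool SNP in
#' the same MAF bin.
#'
#' @param focal data.frame (snp_id, maf_bin, mode, ld_group) — e.g. a
#'   subset of [match_keys()] rows with `mode` set from the eSNP table or
#'   from `proximal`.
#' @param pool data.frame from [match_keys()].
#' @param max_attempts retry cap for LD-multiplicity matching.
#' @return character vector of drawn SNP ids.
#' @export
draw_matched_set <- function(focal, pool, max_attempts = 1000) {
  index <- build_match_index(pool)
  req <- attach_candidates(focal_requirements(focal), index)
  draw_matched_core(req, index, max_attempts)
}

# Normalize a focal specification (ids or keyed frame) against pool keys.
as_focal_keys <- function(focal, pool, focal_modes = NULL) {
  if (is.character(focal)) {
    rows <- pool[match(focal, pool$snp_id), ]
    if (anyNA(rows$snp_id)) stop("focal contains SNPs absent from the pool keys")
    rows$mode <- ifelse(rows$proximal, "cis", "trans")
  } else {
    rows <- focal
    if (is.null(rows$mode)) rows$mode <- ifelse(rows$proximal, "cis", "trans")
  }
  if (!is.null(focal_modes)) {
    hit <- rows$snp_id %in% names(focal_modes)
    rows$mode[hit] <- unname(focal_modes[rows$snp_id[hit]])
  }
  rows
}

# One-hop LD neighbour lists for fast repeated expansion.
neighbour_lists <- function(geno, ids, r_threshold) {
  gs <- geno[, ids, drop = FALSE]
  r <- suppressWarnings(abs(cor(gs)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  lapply(seq_along(ids), function(j) ids[r[, j] > r_threshold])
}

#' Matched-resampling enrichment of a SNP set for low GWAS p-values
#'
#' The observed statistic is the fraction of focal SNPs (after LD expansion
#' when `expand` is given) with GWAS p below `alpha`.  The null is the same
#' statistic over `n_iter` random sets matched on MAF bin, gene proximity
#' and LD multiplicity (and rejection-sampled to within `size_tol` of the
#' expanded focal size when expanding).  Reported are the empirical add-one
#' p-value `(1 + #\{null >= observed\}) / (n_iter + 1)`, the plain strict
#' proportion `p_plain = #\{null > observed\} / n_iter`, and a normal-tail
#' approximation `p_approx` at `z = (observed - null_mean) / null_sd`.
#'
#' @param focal character vector of focal SNP ids (or keyed data.frame).
#' @param pool [match_keys()] table for the candidate pool (restricted
#'   internally to GWAS-scored SNPs).
#' @param gwas data.frame (snp_id, p).
#' @param n_iter number of matched draws (default 1e5; scale down at desk).
#' @param alpha GWAS significance threshold (default 0.05).
#' @param expand optional list(geno, r_threshold = 0.89, size_tol = 0.10,
#'   max_expand_attempts = 1000) enabling expanded-set mode.
#' @param seed RNG seed.
#' @param focal_modes optional named character vector giving the cis/trans
#'   mode of focal SNPs (e.g. from an eSNP table); defaults to proximity.
#' @return object of class `enrichment_result`.
#' @export
enrichment_test <- function(focal, pool, gwas, n_iter = 100000L,
                            alpha = 0.05, expand = NULL, seed = 1L,
                            focal_modes = NULL) {
  scored <- pool$snp_id %in% gwas$snp_id
  pool_s <- pool[scored, ]
  fk <- as_focal_keys(focal, pool, focal_modes)
  drop_n <- sum(!fk$snp_id %in% gwas$snp_id)
  if (drop_n > 0) {
    message(sprintf("dropping %d focal SNPs without GWAS scores", drop_n))
    fk <- fk[fk$snp_id %in% gwas$snp_id, ]
  }
  if (nrow(fk) == 0) stop("no scored focal SNPs", call. = FALSE)
  p_lookup <- gwas$p[match(pool_s$snp_id, gwas$snp_id)]
  names(p_lookup) <- pool_s$snp_id
  sig <- p_lookup < alpha

  expander <- NULL; target_size <- nrow(fk)
  if (!is.null(expand)) {
    nbr <- neighbour_lists(expand$geno, pool_s$snp_id,
                           expand$r_threshold %||% 0.89)
    names(nbr) <- pool_s$snp_id
    expander <- function(ids) unique(c(ids, unlist(nbr[ids], use.names = FALSE)))
    obs_set <- expander(fk$snp_id)
    target_size <- length(obs_set)
    observed <- unname(mean(sig[obs_set]))
  } else {
    observed <- unname(mean(sig[fk$snp_id]))
  }

  index <- build_match_index(pool_s)
  req <- attach_candidates(focal_requirements(fk), index)
  size_tol <- expand$size_tol %||% 0.10
  max_exp <- expand$max_expand_attempts %||% 1000

  null_prop <- with_local_seed(derive_seed(seed, "enrichment"), {
    vapply(seq_len(n_iter), function(it) {
      if (is.null(expander)) {
        ids <- draw_matched_core(req, index)
        mean(sig[ids])
      } else {
        for (att in seq_len(max_exp)) {
          ids <- expander(draw_matched_core(req, index))
          if (abs(length(ids) - target_size) <= size_tol * target_size)
            return(mean(sig[ids]))
        }
        stop(sprintf(paste0("expanded-draw size never entered %.0f%% of %d ",
                            "after %d attempts (last size %d); the pool's LD ",
                            "structure may be too different from the focal set"),
                     100 * size_tol, target_size, max_exp, length(ids)),
             call. = FALSE)
      }
    }, 0)
  })

  null_mean <- mean(null_prop); null_sd <- sd(null_prop)
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  if (null_sd == 0) warning("degenerate null (sd = 0): p_approx undefined")
  structure(list(
    n_snps = target_size, alpha = alpha, observed_prop = observed,
    null_mean = null_mean, null_sd = null_sd,
    ci95 = c(null_mean - 1.96 * null_sd, null_mean + 1.96 * null_sd),
    z = z,
    p_empirical = (1 + sum(null_prop >= observed)) / (n_iter + 1),
    p_plain = sum(null_prop > observed) / n_iter,
    p_approx = if (is.na(z)) NA_real_ else pnorm(z, lower.tail = FALSE),
    fold = if (null_mean > 0) observed / null_mean else NA_real_,
    n_iter = n_iter, n_dropped = drop_n),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Matched-set enrichment (%d SNPs, alpha = %.2g, %d iterations)\n",
              x$n_snps, x$alpha, x$n_iter))
  cat(sprintf("  observed %% below alpha : %.2f%%\n", 100 * x$observed_prop))
  cat(sprintf("  null mean (95%% CI)     : %.2f%% (%.2f%%, %.2f%%)\n",
              100 * x$null_mean, 100 * x$ci95[1], 100 * x$ci95[2]))
  cat(sprintf("  fold = %.2f, Z = %.2f, p_empirical = %.3g, p_approx = %.3g\n",
              x$fold, x$z, x$p_empirical, x$p_approx))
  invisible(x)
}

#' Compare the enrichment of a nested SNP set against its background
#'
#' Draws `n_iter` sets from the background matched to the focal set's
#' stratum histogram and LD multiplicity, and reports the one-sided p for
#' the alternative that the focal set is more enriched than matched picks
#' from the background (the nested set-versus-set design).
#'
#' @inheritParams enrichment_test
#' @param background [match_keys()] table for the background superset.
#' @return list with `p` (empirical add-one p) and `result`
#'   (the full `enrichment_result`).
#' @export
compare_sets <- function(focal, background, gwas, n_iter = 100000L,
                         alpha = 0.05, expand = NULL, seed = 1L,
                         focal_modes = NULL) {
  ids <- if (is.character(focal)) focal else focal$snp_id
  if (!all(ids %in% background$snp_id)) {
    warning("focal set is not nested in the background; dropping the outsiders")
    keep <- ids %in% background$snp_id
    focal <- if (is.character(focal)) focal[keep] else focal[keep, ]
  }
  res <- enrichment_test(focal, background, gwas, n_iter = n_iter,
                         alpha = alpha, expand = expand, seed = seed,
                         focal_modes = focal_modes)
  list(p = res$p_empirical, result = res)
}
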