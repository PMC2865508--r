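# Pairwise LD on allele-count codes, single-linkage LD grouping, one-hop
# set expansion at |r| > 0.89, and MAF binning for matched resampling.

#' Absolute genotype correlation between two SNPs
#'
#' Pearson correlation of 0/1/2 allele counts over shared non-missing
#' samples, returned as an absolute value ("correlation > 0.89" is read as
#' |r| on genotype codes, not r squared, so no phasing is needed).
#'
#' @param g1,g2 genotype vectors.
#' @return absolute Pearson correlation.
#' @export
ld_corr <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  if (sum(keep) < 3) stop("fewer than 3 overlapping non-missing samples",
                          call. = FALSE)
  a <- g1[keep]; b <- g2[keep]
  if (sd(a) == 0 || sd(b) == 0)
    stop("monomorphic genotype vector: correlation undefined", call. = FALSE)
  abs(cor(a, b))
}

#' Assign SNPs to LD groups by single-linkage within a positional window
#'
#' Two SNPs on the same chromosome within `window` bp are joined when their
#' absolute genotype correlation exceeds `r_threshold`; LD groups are the
#' connected components of that graph (single linkage: a chain A-B-C with
#' both links above threshold is one group even if |r(A,C)| is below it).
#'
#' @param geno samples x SNPs matrix.
#' @param snps SNP table sorted by (chrom, pos).
#' @param r_threshold exclusive correlation threshold (default 0.89).
#' @param window positional window in bp (default 1 Mb).
#' @return integer vector of group ids, named by snp_id.
#' @export
ld_groups <- function(geno, snps, r_threshold = 0.89, window = 1e6) {
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("SNP table must be sorted by (chrom, pos)", call. = FALSE)
  n_snp <- nrow(snps)
  parent <- seq_len(n_snp)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    if (length(idx) < 2) next
    gs <- scale(geno[, idx, drop = FALSE])
    pos <- snps$pos[idx]
    for (i in seq_along(idx)[-length(idx)]) {
      js <- which(pos > pos[i] & pos - pos[i] <= window)
      js <- js[js > i]
      if (!length(js)) next
      r <- abs(crossprod(gs[, i], gs[, js, drop = FALSE])) / (nrow(gs) - 1)
      hits <- js[which(r > r_threshold)]
      for (j in hits) {
        ri <- find(idx[i]); rj <- find(idx[j])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n_snp), find, 0L)
  out <- match(roots, unique(roots))
  names(out) <- snps$snp_id
  out
}

#' Expand a SNP set by one hop of strong LD
#'
#' The expanded set is the core plus every panel SNP whose absolute
#' genotype correlation with at least one core member exceeds
#' `r_threshold`.  Expansion is one hop only (not closed under iteration).
#'
#' @param core character vector of core SNP ids.
#' @param geno samples x SNPs matrix.
#' @param snps SNP table.
#' @param r_threshold exclusive threshold (default 0.89).
#' @return list of class `ld_expansion`: `core_set`, `expanded_set`,
#'   `r_threshold`, and `anchors` (for each added SNP, one core SNP
#'   certifying the anchoring correlation).
#' @export
expand_set <- function(core, geno, snps, r_threshold = 0.89) {
  core <- unique(core)
  if (length(core) == 0) {
    warning("empty core set: expansion is empty")
    return(structure(list(core_set = character(), expanded_set = character(),
                          r_threshold = r_threshold,
                          anchors = data.frame(snp_id = character(),
                                               anchor = character(),
                                               r = numeric())),
                     class = "ld_expansion"))
  }
  if (!all(core %in% snps$snp_id)) stop("core contains SNPs absent from the panel")
  others <- setdiff(snps$snp_id, core)
  r <- suppressWarnings(abs(cor(geno[, others, drop = FALSE],
                                geno[, core, drop = FALSE])))
  r[is.na(r)] <- 0
  best <- apply(r, 1, which.max)
  bestr <- r[cbind(seq_len(nrow(r)), best)]
  added <- which(bestr > r_threshold)
  anchors <- data.frame(snp_id = others[added], anchor = core[best[added]],
                        r = bestr[added], stringsAsFactors = FALSE)
  structure(list(core_set = core,
                 expanded_set = sort(union(core, others[added])),
                 r_threshold = r_threshold, anchors = anchors),
            class = "ld_expansion")
}

#' @export
print.ld_expansion <- function(x, ...) {
  cat(sprintf("LD expansion at |r| > %.2f: %d core -> %d expanded (+%d proxies)\n",
              x$r_threshold, length(x$core_set), length(x$expanded_set),
              length(x$expanded_set) - length(x$core_set)))
  invisible(x)
}

#' Bin a minor allele frequency into the five matching strata
#'
#' Half-open right-closed bins: (5,10], (10,20], (20,30], (30,40], (40,50]
#' percent.  MAF at or below 5% (or above 50%) is ineligible and errors.
#'
#' @param maf numeric vector of minor allele frequencies (fractions).
#' @return integer bin indices 1-5.
#' @export
maf_bin <- function(maf) {
  if (any(is.na(maf)) || any(maf <= 0.05) || any(maf > 0.5))
    stop("MAF must lie in (0.05, 0.5]: SNPs at or below 5% are ineligible",
         call. = FALSE)
  as.integer(cut(maf, breaks = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
                 right = TRUE, labels = FALSE))
}
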