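# Readers and writers for the pipeline's interchange formats (TSV with
# header row; "NA" for missing), minimal VCF GT support, GMT gene sets,
# study-bundle loading and validation.

write_tsv_file <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_col), as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a genotype matrix as TSV (samples x SNPs, codes 0/1/2)
#'
#' The first column (`sample`) holds sample identifiers; missing genotypes
#' are written as "NA".  Reading validates every code and reports the
#' offending row and column on failure.
#'
#' @param geno samples x SNPs integer matrix.
#' @param path file path.
#' @return `read_genotypes_tsv` returns the validated matrix.
#' @export
write_genotypes_tsv <- function(geno, path) {
  write_tsv_file(geno, path, rownames_col = "sample")
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(m %in% c(0, 1, 2, NA)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid genotype code %s at row %d (sample %s), column %s",
                 m[bad[1]], rc[1], df[[1]][rc[1]], colnames(m)[rc[2]]),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a numeric matrix (expression) as TSV with a sample column
#' @param mat samples x genes matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  write_tsv_file(mat, path, rownames_col = "sample")
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the simple tables of the pipeline (SNPs, genes, GWAS, ...)
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) write_tsv_file(df, path)

#' @rdname write_table_tsv
#' @param required optional character vector of required column names.
#' @export
read_table_tsv <- function(path, required = NULL) {
  df <- read_tsv_file(path)
  if (!is.null(required) && !all(required %in% names(df)))
    stop(sprintf("%s: missing required columns %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")),
         call. = FALSE)
  df
}

#' Minimal VCF output (GT field only) for a genotype matrix
#'
#' @param geno samples x SNPs matrix of 0/1/2 allele counts.
#' @param snps SNP table (snp_id, chrom, pos).
#' @param path output path (plain text).
#' @export
write_vcf_minimal <- function(geno, snps, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
}

#' Read allele-count genotypes from a VCF (GT extraction via vcfR)
#'
#' @param path VCF path.
#' @return samples x SNPs matrix of 0/1/2 allele counts (NA for missing).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  })
  t(counts)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, "", 1))
}

#' Load and validate a study bundle from a YAML configuration
#'
#' The configuration maps input roles (geno, snps, genes, expr, gwas,
#' gene_sets, orthologs, cross_dir) to file paths.  Sample identifiers must
#' agree between genotype and expression; SNP identifiers are
#' cross-checked between genotype, SNP table and GWAS, with mismatch
#' counts reported (strict mode aborts on any mismatch).
#'
#' @param config_path YAML file path; relative input paths are resolved
#'   against the YAML's directory.
#' @param strict abort on identifier mismatches instead of warning.
#' @return list of class `study_bundle` with the parsed inputs and a
#'   `provenance` block.
#' @export
load_study <- function(config_path, strict = FALSE) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  pth <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base, p)
  bundle <- list(provenance = cfg$provenance %||% list())
  if (!is.null(cfg$geno)) bundle$geno <- read_genotypes_tsv(pth(cfg$geno))
  if (!is.null(cfg$snps))
    bundle$snps <- read_table_tsv(pth(cfg$snps),
                                  c("snp_id", "chrom", "pos", "maf"))
  if (!is.null(cfg$genes))
    bundle$genes <- read_table_tsv(pth(cfg$genes),
                                   c("gene_id", "chrom", "start", "stop"))
  if (!is.null(cfg$expr)) bundle$expr <- read_matrix_tsv(pth(cfg$expr))
  if (!is.null(cfg$gwas))
    bundle$gwas <- read_table_tsv(pth(cfg$gwas), c("snp_id", "p"))
  if (!is.null(cfg$orthologs))
    bundle$orthologs <- read_table_tsv(pth(cfg$orthologs),
                                       c("mouse_id", "human_id"))
  if (!is.null(cfg$gene_sets)) bundle$gene_sets <- read_gmt(pth(cfg$gene_sets))

  if (!is.null(bundle$snps) && anyDuplicated(bundle$snps$snp_id))
    stop("duplicate SNP ids in the SNP table", call. = FALSE)
  report <- function(what, n_bad, n_all) {
    if (n_bad == 0) return(invisible())
    msg <- sprintf("%s: %d of %d identifiers unmatched", what, n_bad, n_all)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!is.null(bundle$geno) && !is.null(bundle$expr))
    report("geno/expr samples",
           sum(!(rownames(bundle$geno) %in% rownames(bundle$expr))),
           nrow(bundle$geno))
  if (!is.null(bundle$geno) && !is.null(bundle$snps))
    report("geno/snp-table SNPs",
           sum(!(colnames(bundle$geno) %in% bundle$snps$snp_id)),
           ncol(bundle$geno))
  if (!is.null(bundle$gwas) && !is.null(bundle$snps))
    report("snp-table/GWAS SNPs",
           sum(!(bundle$snps$snp_id %in% bundle$gwas$snp_id)),
           nrow(bundle$snps))
  structure(bundle, class = "study_bundle")
}

#' Write a simulated study to a directory of TSV files
#'
#' Emits the genotype matrix, SNP table (snp_id, chrom, pos, maf), gene
#' annotations, expression matrix, GWAS table, truth annotations, the F2
#' cross bundle, and a `study.yaml` usable with [load_study()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_genotypes(config)
  expr <- simulate_expression(panel$geno, panel$snps, panel$genes, config)
  gwas <- simulate_gwas(panel$geno, panel$snps, config,
                        driver_snps = attr(expr, "drivers")$snp_id)
  cross <- simulate_f2_cross(config)

  write_genotypes_tsv(panel$geno, file.path(out_dir, "genotypes.tsv"))
  write_table_tsv(panel$snps[, c("snp_id", "chrom", "pos", "maf")],
                  file.path(out_dir, "snps.tsv"))
  write_table_tsv(panel$genes, file.path(out_dir, "genes.tsv"))
  write_matrix_tsv(expr, file.path(out_dir, "expression.tsv"))
  write_table_tsv(gwas, file.path(out_dir, "gwas.tsv"))
  write_table_tsv(attr(expr, "esnp_pairs"),
                  file.path(out_dir, "truth_esnp_pairs.tsv"))
  write_table_tsv(attr(expr, "modules"),
                  file.path(out_dir, "truth_modules.tsv"))
  write_table_tsv(attr(expr, "drivers"),
                  file.path(out_dir, "truth_drivers.tsv"))
  cd <- file.path(out_dir, "cross")
  dir.create(cd, showWarnings = FALSE)
  write_genotypes_tsv(cross$geno, file.path(cd, "genotypes.tsv"))
  write_table_tsv(cross$map, file.path(cd, "map.tsv"))
  write_matrix_tsv(cross$expr, file.path(cd, "expression.tsv"))
  write_tsv_file(cross$traits, file.path(cd, "traits.tsv"),
                 rownames_col = "sample")
  yaml::write_yaml(list(geno = "genotypes.tsv", snps = "snps.tsv",
                        genes = "genes.tsv", expr = "expression.tsv",
                        gwas = "gwas.tsv", cross_dir = "cross",
                        provenance = list(seed = config$seed)),
                   file.path(out_dir, "study.yaml"))
  invisible(list(panel = panel, expr = expr, gwas = gwas, cross = cross))
}
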