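# Expression-matrix construction: prevalence filter on raw counts, pseudogene
# exclusion by biotype, COSMIC cancer-gene rescue, median-of-ratios size
# factors, FPM normalisation and log2(x + 1) transform.

#' Prevalence filter on raw counts
#'
#' A gene is retained when its count is strictly above `min_count` in at
#' least `ceiling(min_fraction * n_samples)` samples.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param min_count count threshold (default 10, strict `>`).
#' @param min_fraction required fraction of samples (default 0.9).
#' @return character vector of retained gene names.
#' @export
filter_genes <- function(counts, min_count = 10, min_fraction = 0.9) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0)
    stopf("validation error: empty count matrix")
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts > min_count) >= need
  rownames(counts)[keep]
}

#' Exclude pseudogene-class genes
#'
#' Any biotype containing the substring "pseudogene" (case-insensitive) is
#' excluded.
#'
#' @param genes character vector of gene names.
#' @param gene_meta data frame with `gene` and `biotype` columns covering all
#'   of `genes`.
#' @return the genes whose biotype is not pseudogene-associated.
#' @export
exclude_pseudogenes <- function(genes, gene_meta) {
  biotype <- gene_meta$biotype[match(genes, gene_meta$gene)]
  if (anyNA(biotype))
    stopf("validation error: missing biotype for genes: %s",
          paste(genes[is.na(biotype)][1:min(5, sum(is.na(biotype)))],
                collapse = ", "))
  genes[!grepl("pseudogene", biotype, ignore.case = TRUE)]
}

#' Rescue COSMIC cancer genes into the retained set
#'
#' Genes with a COSMIC role (oncogene or TSG) are reimported regardless of
#' prevalence or pseudogene status, so every cancer-related gene expressed in
#' the cohort is represented. Provenance records whether each final gene was
#' kept by prevalence or re-added by the rescue.
#'
#' @param retained genes surviving prevalence + pseudogene filters.
#' @param gene_meta data frame with `gene` and `cosmic_role` columns for the
#'   full gene universe.
#' @return a list with `genes` (final set, in gene-universe order) and
#'   `provenance` (data frame gene / reason, reason in
#'   `c("prevalence", "cosmic_rescue")`).
#' @export
rescue_cancer_genes <- function(retained, gene_meta) {
  cosmic <- gene_meta$gene[gene_meta$cosmic_role %in% c("oncogene", "TSG")]
  final <- gene_meta$gene[gene_meta$gene %in% union(retained, cosmic)]
  reason <- ifelse(final %in% retained, "prevalence", "cosmic_rescue")
  list(genes = final,
       provenance = data.frame(gene = final, reason = reason,
                               stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes of the ratio of its
#' count to the gene's geometric mean across samples; only genes with a
#' positive count in every sample enter. Identical columns give factors of 1.
#'
#' @param counts genes x samples matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1)
    return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf(paste("normalization error: no gene has positive counts in every",
                "sample; consider a pseudo-reference fallback"))
  logc <- log(counts[pos, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - log_geo)))
  stats::setNames(sf, colnames(counts))
}

#' FPM (fragments per million) normalisation with robust library size
#'
#' `FPM[g, j] = count[g, j] / (factor[j] * Lbar) * 1e6`, where `Lbar` is the
#' mean over samples of `library_size[j] / factor[j]`. With all factors equal
#' to 1 this reduces to counts per million and every column sums to 1e6.
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample size factors (positive).
#' @return genes x samples FPM matrix.
#' @export
fpm_normalize <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (any(factors <= 0)) stopf("normalization error: non-positive size factor")
  if (length(factors) != ncol(counts))
    stopf("normalization error: %d factors for %d samples",
          length(factors), ncol(counts))
  lbar <- mean(colSums(counts) / factors)
  if (lbar == 0) stopf("normalization error: matrix has no reads")
  sweep(counts, 2, factors * lbar, "/") * 1e6
}

#' log2(x + 1) transform
#' @param matrix non-negative matrix (FPM scale).
#' @return the transformed matrix.
#' @export
log_transform <- function(matrix) {
  if (any(matrix < 0)) stopf("log transform requires non-negative values")
  log2(matrix + 1)
}

#' Build the analysis-ready expression matrix from raw counts
#'
#' Composes the prevalence filter, pseudogene exclusion, COSMIC rescue,
#' median-of-ratios size factors, FPM normalisation and log2(x + 1)
#' transform.
#'
#' @param counts genes x samples integer matrix.
#' @param gene_meta gene metadata (`gene`, `biotype`, `cosmic_role`).
#' @param min_count,min_fraction prevalence parameters (defaults 10 and 0.9).
#' @return a list of class `expression_matrix` with `log2fpm`, `fpm`,
#'   `size_factors`, `genes` and `provenance`.
#' @export
build_expression_matrix <- function(counts, gene_meta, min_count = 10,
                                    min_fraction = 0.9) {
  retained <- filter_genes(counts, min_count, min_fraction)
  retained <- exclude_pseudogenes(retained, gene_meta)
  rescued <- rescue_cancer_genes(retained, gene_meta)
  sub <- counts[rescued$genes, , drop = FALSE]
  sf <- size_factors_median_of_ratios(counts)  # factors from the full matrix
  fpm <- fpm_normalize(sub, sf)
  structure(list(log2fpm = log_transform(fpm), fpm = fpm, size_factors = sf,
                 genes = rescued$genes, provenance = rescued$provenance),
            class = "expression_matrix")
}

#' Write an expression matrix (log2 FPM) as TSV
#' @param em an `expression_matrix` (or a plain matrix).
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_expression_tsv <- function(em, path, fingerprint = NULL) {
  mat <- if (inherits(em, "expression_matrix")) em$log2fpm else em
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stable(df, path, fingerprint)
}

#' Read a TSV count or expression matrix (genes as rows)
#'
#' The first column must be `gene`; optional `biotype` / `cosmic_role`
#' metadata columns are split out.
#' @param path file to read.
#' @return a list with `matrix` and `gene_meta` (NULL when no metadata
#'   columns are present).
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_stable(path)
  meta_cols <- intersect(c("biotype", "cosmic_role"), names(df))
  sample_cols <- setdiff(names(df), c("gene", meta_cols))
  mat <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(mat) <- df$gene
  gene_meta <- if (length(meta_cols))
    cbind(data.frame(gene = df$gene, stringsAsFactors = FALSE),
          df[, meta_cols, drop = FALSE])
  else NULL
  list(matrix = mat, gene_meta = gene_meta)
}
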