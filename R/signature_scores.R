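# Per-sample score panel: BRAF-RAS score (BRS) from distances to
# mutation-typed reference centroids on a 71-gene signature, thyroid
# differentiation score (TDS, 16 genes) and ERK score (52 genes) as means of
# median-centred log2 FPM, and tumour mutation burden (TMB) per megabase.

#' Fit BRAF and RAS reference centroids
#'
#' One centroid per mutation-typed reference group on the FPM profiles of
#' the signature genes. With the groups fixed by mutation status, k-means
#' within a group is degenerate at k = 1, so each centroid is the group mean
#' vector.
#'
#' @param reference_fpm genes x samples FPM matrix of the labelled reference.
#' @param labels named vector over the reference samples with values
#'   `"BRAF"` and `"RAS"`.
#' @param signature character vector of signature gene symbols (the BRS
#'   signature, 71 genes by default).
#' @return a list with `centroid_braf`, `centroid_ras` (named vectors over
#'   the signature genes) and `genes`.
#' @export
fit_centroids <- function(reference_fpm, labels, signature) {
  missing_genes <- setdiff(signature, rownames(reference_fpm))
  if (length(missing_genes))
    stopf("signature genes absent from reference matrix: %s",
          paste(missing_genes, collapse = ", "))
  labels <- labels[colnames(reference_fpm)]
  for (grp in c("BRAF", "RAS")) {
    if (!any(labels == grp, na.rm = TRUE))
      stopf("centroid fitting requires at least one '%s'-labelled sample", grp)
  }
  sub <- reference_fpm[signature, , drop = FALSE]
  list(centroid_braf = rowMeans(sub[, labels == "BRAF", drop = FALSE]),
       centroid_ras = rowMeans(sub[, labels == "RAS", drop = FALSE]),
       genes = signature)
}

#' BRAF-RAS score (BRS)
#'
#' For each sample, the difference between its Euclidean distance to the BRAF
#' centroid and to the RAS centroid on the signature genes (FPM scale),
#' scaled by the cohort's maximum absolute difference so scores span
#' `[-1, 1]`. Negative scores mean the expression pattern resembles a BRAF
#' V600E tumour; positive, a RAS tumour. A degenerate cohort in which every
#' raw difference is zero scores 0 everywhere.
#'
#' @param samples_fpm genes x samples FPM matrix of the cohort to score.
#' @param centroids a [fit_centroids()] result.
#' @return named numeric vector of BRS values in `[-1, 1]`.
#' @export
brs_score <- function(samples_fpm, centroids) {
  if (ncol(samples_fpm) == 0) stopf("empty cohort")
  missing_genes <- setdiff(centroids$genes, rownames(samples_fpm))
  if (length(missing_genes))
    stopf("signature genes absent from cohort matrix: %s",
          paste(missing_genes, collapse = ", "))
  sub <- samples_fpm[centroids$genes, , drop = FALSE]
  d_braf <- sqrt(colSums((sub - centroids$centroid_braf)^2))
  d_ras <- sqrt(colSums((sub - centroids$centroid_ras)^2))
  raw <- d_braf - d_ras
  m <- max(abs(raw))
  if (m == 0) return(stats::setNames(rep(0, ncol(sub)), colnames(sub)))
  stats::setNames(raw / m, colnames(sub))
}

#' Thyroid differentiation score (TDS)
#'
#' Per gene, FPM values are log2(x + 1) transformed and centred by the gene's
#' median across the scored cohort; a sample's score is the mean of the
#' centred values over the signature genes. Lower TDS means less
#' differentiated.
#'
#' @param fpm genes x samples FPM matrix.
#' @param signature character vector of signature genes (16 thyroid-function
#'   genes for TDS).
#' @return named numeric vector of scores.
#' @export
tds_score <- function(fpm, signature) {
  missing_genes <- setdiff(signature, rownames(fpm))
  if (length(missing_genes))
    stopf("signature genes absent from matrix: %s",
          paste(missing_genes, collapse = ", "))
  lg <- log2(fpm[signature, , drop = FALSE] + 1)
  centred <- lg - apply(lg, 1, stats::median)
  stats::setNames(colMeans(centred), colnames(fpm))
}

#' ERK score
#'
#' Identical computation to [tds_score()] over the ERK-related MAPK pathway
#' gene list (52 genes); higher means more MAPK pathway output.
#'
#' @param fpm genes x samples FPM matrix.
#' @param signature character vector of ERK pathway genes.
#' @return named numeric vector of scores.
#' @export
erk_score <- function(fpm, signature) {
  tds_score(fpm, signature)
}

#' Tumour mutation burden (TMB)
#'
#' Retained non-synonymous mutations (everything except silent calls,
#' including InDels) divided by the capture size in megabases.
#'
#' @param variant_counts named per-sample counts of retained non-synonymous
#'   variants, or a retained variant-record data frame (silent calls are then
#'   excluded and counted per sample).
#' @param capture_size_mb capture size in Mb (default 50).
#' @param samples optional sample ids to report (zero-count samples
#'   included); defaults to the names/samples present.
#' @return named numeric vector of TMB values (mutations/Mb).
#' @export
tmb <- function(variant_counts, capture_size_mb = 50, samples = NULL) {
  if (capture_size_mb <= 0) stopf("capture size must be positive")
  if (is.data.frame(variant_counts)) {
    rec <- variant_counts[variant_counts$variant_class != "silent", ,
                          drop = FALSE]
    samples <- samples %||% sort(unique(variant_counts$sample_id))
    counts <- stats::setNames(rep(0, length(samples)), samples)
    if (nrow(rec)) {
      tab <- table(rec$sample_id)
      keep <- intersect(names(tab), samples)
      counts[keep] <- as.numeric(tab[keep])
    }
  } else {
    counts <- variant_counts
    if (!is.null(samples)) {
      full <- stats::setNames(rep(0, length(samples)), samples)
      full[names(counts)] <- counts
      counts <- full
    }
  }
  counts / capture_size_mb
}

#' Read a signature gene list (one symbol per line)
#' @param path plain-text file, one gene symbol per line; blank lines and
#'   `#` comments ignored.
#' @return character vector of gene symbols.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a per-sample score panel as TSV
#' @param panel data frame with `sample_id`, `BRS`, `TDS`, `ERK`, `TMB`.
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_score_panel <- function(panel, path, fingerprint = NULL) {
  write_tsv_stable(panel[, c("sample_id", "BRS", "TDS", "ERK", "TMB")],
                   path, fingerprint)
}
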