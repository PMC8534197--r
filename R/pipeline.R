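# End-to-end orchestration: generate or ingest a cohort, run the variant and
# fusion filter chains, build the expression matrix, infer clusters and
# BL/RL assignments, compute the score panel, and emit a cohort report with
# per-stage record-count logging and a config fingerprint in every file.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: variant filters (mapping
#' quality 20, population allele frequency 0.001), fusion filters (FFPM 0.1,
#' read support 10), expression prevalence (count 10 in 90% of samples),
#' Hopkins bootstrap (512 replicates, probe fraction 0.1, 10 components),
#' consensus-k bootstrap (1080 replicates, 10% of genes, k in 2..8), outlier
#' threshold (3 SD) and TMB capture size (50 Mb). In synthetic mode the
#' cohort comes from [cohort_config()]; otherwise `inputs` holds file paths.
#'
#' @param synthetic generate the cohort with the built-in simulator.
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param inputs named list of paths (file mode): `counts`, `variants`,
#'   `fusions`, `annotations`, `reference_counts`, `reference_labels`,
#'   `signature_brs`, `signature_tds`, `signature_erk`, `fusion_blacklist`,
#'   `normal_variants`.
#' @param min_qc,max_af variant-filter thresholds.
#' @param min_ffpm,min_support,support_mode fusion-filter parameters.
#' @param min_count,min_fraction expression prevalence parameters.
#' @param reps_hopkins,probe_fraction,n_components Hopkins parameters.
#' @param reps_consensus,gene_fraction,k_max consensus-k parameters.
#' @param z_outlier outlier threshold in SD units.
#' @param capture_size_mb TMB capture size.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            cohort = cohort_config(),
                            inputs = list(),
                            min_qc = 20, max_af = 0.001,
                            min_ffpm = 0.1, min_support = 10,
                            support_mode = "each",
                            min_count = 10, min_fraction = 0.9,
                            reps_hopkins = 512, probe_fraction = 0.1,
                            n_components = 10,
                            reps_consensus = 1080, gene_fraction = 0.1,
                            k_max = 8,
                            z_outlier = 3,
                            capture_size_mb = 50,
                            seed = 1L) {
  structure(list(synthetic = isTRUE(synthetic), cohort = cohort,
                 inputs = inputs,
                 min_qc = as.numeric(min_qc), max_af = as.numeric(max_af),
                 min_ffpm = as.numeric(min_ffpm),
                 min_support = as.numeric(min_support),
                 support_mode = support_mode,
                 min_count = as.numeric(min_count),
                 min_fraction = as.numeric(min_fraction),
                 reps_hopkins = as.integer(reps_hopkins),
                 probe_fraction = as.numeric(probe_fraction),
                 n_components = as.integer(n_components),
                 reps_consensus = as.integer(reps_consensus),
                 gene_fraction = as.numeric(gene_fraction),
                 k_max = as.integer(k_max),
                 z_outlier = as.numeric(z_outlier),
                 capture_size_mb = as.numeric(capture_size_mb),
                 seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly through its file representation.
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  # named atomic vectors become YAML maps (as lists) so names survive;
  # 17 significant digits round-trip IEEE doubles losslessly
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(unclass(config)), path, precision = 17)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- raw$cohort
  if (!is.null(cohort)) {
    cohort$n_signature_genes <- unlist(cohort$n_signature_genes)
    cohort$archetype_fractions <- unlist(cohort$archetype_fractions)
    cohort$fusion_rate_by_archetype <- unlist(cohort$fusion_rate_by_archetype)
    cohort$library_size_range <- unlist(cohort$library_size_range)
    raw$cohort <- do.call(cohort_config, cohort)
  }
  args <- raw[setdiff(names(raw), "cohort")]
  do.call(pipeline_config, c(args, list(cohort = raw$cohort %||%
                                          cohort_config())))
}

log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[%s] records in: %d, out: %d", stage, n_in, n_out))
}

#' Run the full profiling pipeline
#'
#' Variant filter chain, fusion filters, expression-matrix construction,
#' clusterability test, consensus-k, WPGMA clustering, PCA, outlier
#' exclusion, BL/RL assignment of driver-negative samples, and the
#' BRS/TDS/ERK/TMB score panel. Outlier samples are excluded from clustering
#' and group summaries but still scored. Every output file carries the
#' configuration fingerprint; every stage logs record counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return invisibly, a list with all intermediate and final objects:
#'   `truth`, `variant` (retained/audit), `fusions`, `expression`,
#'   `cluster` (hopkins, consensus, labels, pca, outliers, assignments),
#'   `scores`, `groups`, `group_summary`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  fp <- config_fingerprint(unclass(config))
  seed <- config$seed

  if (config$synthetic) {
    cc <- config$cohort
    cohort <- generate_counts(cc)
    truth <- cohort$truth
    variants <- generate_variant_table(cc, truth)
    fusions <- generate_fusion_table(cc, truth)
    reference <- generate_reference_matrix(cc)
    gene_meta <- cohort$gene_meta
    counts <- cohort$counts
    normal <- normal_set_from_flags(variants)
    blacklist <- normal_fusion_pairs()
    sig <- list(BRS = signature_genes(gene_meta, "BRS"),
                TDS = signature_genes(gene_meta, "TDS"),
                ERK = signature_genes(gene_meta, "ERK"))
    annotations <- truth[, c("sample_id", "driver_status")]
    annotations$histology <- NA_character_
  } else {
    inp <- config$inputs
    need <- c("counts", "variants", "fusions", "annotations",
              "reference_counts", "reference_labels",
              "signature_brs", "signature_tds", "signature_erk")
    miss <- setdiff(need, names(inp))
    if (length(miss))
      stopf("missing inputs: %s", paste(miss, collapse = ", "))
    cm <- read_matrix_tsv(inp$counts)
    counts <- cm$matrix
    gene_meta <- cm$gene_meta %||%
      stopf("count matrix must carry biotype/cosmic_role metadata columns")
    variants <- read_variants_maf(inp$variants)
    fusions <- read_fusions_tsv(inp$fusions)
    annotations <- read_tsv_stable(inp$annotations)
    if (!"histology" %in% names(annotations))
      annotations$histology <- NA_character_
    rm_ <- read_matrix_tsv(inp$reference_counts)
    ref_labels_df <- read_tsv_stable(inp$reference_labels)
    ref_labels <- stats::setNames(ref_labels_df$label,
                                  ref_labels_df$sample_id)
    ref_sf <- size_factors_median_of_ratios(rm_$matrix)
    reference <- list(fpm = fpm_normalize(rm_$matrix, ref_sf),
                      labels = ref_labels)
    sig <- list(BRS = read_signature(inp$signature_brs),
                TDS = read_signature(inp$signature_tds),
                ERK = read_signature(inp$signature_erk))
    normal <- if (!is.null(inp$normal_variants))
      normal_variant_set(read_tsv_stable(inp$normal_variants))
    else if ("normal_shared" %in% names(variants))
      normal_set_from_flags(variants)
    else normal_variant_set(character(0))
    blacklist <- if (!is.null(inp$fusion_blacklist))
      read_tsv_stable(inp$fusion_blacklist)
    else data.frame(gene5 = character(0), gene3 = character(0))
    truth <- NULL
  }
  samples <- colnames(counts)
  driver_status <- stats::setNames(annotations$driver_status,
                                   annotations$sample_id)
  histology <- stats::setNames(annotations$histology, annotations$sample_id)

  # -- variant filter chain ---------------------------------------------------
  vf <- run_variant_filter_chain(variants, normal,
                                 min_qc = config$min_qc,
                                 max_af = config$max_af)
  log_stage("variant_filter", nrow(variants), nrow(vf$retained))

  # -- fusion filters ---------------------------------------------------------
  fus <- filter_fusions(fusions, min_ffpm = config$min_ffpm,
                        min_support = config$min_support,
                        support_mode = config$support_mode)
  fus <- subtract_normal_fusions(fus, blacklist)
  log_stage("fusion_filter", nrow(fusions), sum(fus$status == "pass"))

  # -- expression matrix ------------------------------------------------------
  em <- build_expression_matrix(counts, gene_meta,
                                min_count = config$min_count,
                                min_fraction = config$min_fraction)
  log_stage("expression_matrix", nrow(counts), nrow(em$log2fpm))

  # -- clustering -------------------------------------------------------------
  outliers <- flag_outliers(em$log2fpm, config$z_outlier)
  core <- setdiff(samples, outliers)
  core_mat <- em$log2fpm[, core, drop = FALSE]
  hop <- bootstrapped_clusterability(core_mat, reps = config$reps_hopkins,
                                     probe_fraction = config$probe_fraction,
                                     n_components = config$n_components,
                                     seed = substream_seed(seed, "hopkins"))
  cons <- consensus_cluster_number(core_mat,
                                   k_range = 2:min(config$k_max,
                                                   length(core) - 1L),
                                   reps = config$reps_consensus,
                                   gene_fraction = config$gene_fraction,
                                   seed = substream_seed(seed, "consensus"))
  wp <- wpgma_cluster(core_mat, cons$chosen_k)
  pca <- pca_project(em$log2fpm, 2)
  assignments <- assign_negative_classes(wp$labels, driver_status, histology)
  log_stage("cluster_inference", length(samples), length(core))

  # -- scores -----------------------------------------------------------------
  centroids <- fit_centroids(reference$fpm, reference$labels, sig$BRS)
  panel <- data.frame(
    sample_id = samples,
    BRS = as.numeric(brs_score(em$fpm, centroids)[samples]),
    TDS = as.numeric(tds_score(em$fpm, sig$TDS)[samples]),
    ERK = as.numeric(erk_score(em$fpm, sig$ERK)[samples]),
    TMB = as.numeric(tmb(vf$retained, config$capture_size_mb,
                         samples = samples)[samples]),
    stringsAsFactors = FALSE)
  log_stage("signature_scores", length(samples), nrow(panel))

  # -- grouping and summaries -------------------------------------------------
  groups <- stats::setNames(rep(NA_character_, length(samples)), samples)
  groups[driver_status[samples] == "positive-BRAF"] <- "BRAF-positive"
  groups[driver_status[samples] %in%
           c("positive-RAS", "positive-PAX8-PPARg")] <-
    "RAS/PAX8-PPARg-positive"
  groups[names(assignments)] <- assignments
  core_groups <- groups[core]
  per_sample_fus <- fusion_counts_per_sample(fus, samples)
  summary_tab <- summarize_groups(panel[panel$sample_id %in% core, ],
                                  core_groups, per_sample_fus[core])
  burden <- fusion_burden(fus[fus$sample_id %in% core, , drop = FALSE],
                          core_groups)

  cluster_report <- data.frame(
    sample_id = samples,
    cluster = ifelse(samples %in% core,
                     as.integer(wp$labels[samples]), NA_integer_),
    group = as.character(groups[samples]),
    PC1 = pca[samples, 1], PC2 = pca[samples, 2],
    outlier = samples %in% outliers,
    stringsAsFactors = FALSE)

  summary <- list(config_fingerprint = fp,
                  hopkins_mean_one_minus_h = hop$mean_one_minus_h,
                  clusterable = hop$clusterable,
                  per_k_votes = as.list(cons$per_k_votes),
                  chosen_k = cons$chosen_k,
                  n_outliers = length(outliers),
                  group_sizes = as.list(table(core_groups)),
                  group_mean_tmb = stats::setNames(
                    as.list(summary_tab$mean_tmb), summary_tab$group),
                  group_mean_fusions = stats::setNames(
                    as.list(burden$mean_fusions), burden$group))

  result <- list(truth = truth, variant = vf, fusions = fus,
                 expression = em,
                 cluster = list(hopkins = hop, consensus = cons,
                                labels = wp$labels, tree = wp$tree,
                                pca = pca, outliers = outliers,
                                assignments = assignments),
                 scores = panel, groups = groups,
                 group_summary = summary_tab, summary = summary,
                 fingerprint = fp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_audit(vf$audit, file.path(out_dir, "variant_audit.tsv"), fp)
    write_fusion_audit(fus, file.path(out_dir, "fusion_audit.tsv"), fp)
    write_expression_tsv(em, file.path(out_dir, "expression_matrix.tsv"), fp)
    write_tsv_stable(cluster_report,
                     file.path(out_dir, "cluster_report.tsv"), fp)
    write_score_panel(panel, file.path(out_dir, "score_panel.tsv"), fp)
    write_tsv_stable(summary_tab,
                     file.path(out_dir, "group_summary.tsv"), fp)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$synthetic)
      write_truth_tsv(truth, file.path(out_dir, "truth.tsv"), fp)
  }
  invisible(result)
}

fusion_counts_per_sample <- function(fusion_records, samples) {
  passing <- fusion_records[fusion_records$status == "pass", , drop = FALSE]
  counts <- stats::setNames(rep(0, length(samples)), samples)
  if (nrow(passing)) {
    tab <- table(passing$sample_id)
    keep <- intersect(names(tab), samples)
    counts[keep] <- as.numeric(tab[keep])
  }
  counts
}

#' Per-group cohort summary
#'
#' For each group: sample count and mean TMB, fusion burden, BRS, TDS and
#' ERK. Groups listed in `all_groups` but absent from the data are reported
#' with `n = 0` and missing means.
#'
#' @param score_panel data frame with `sample_id`, `BRS`, `TDS`, `ERK`,
#'   `TMB`.
#' @param groups named group labels over the scored samples.
#' @param per_sample_fusions optional named passing-fusion counts per sample.
#' @param all_groups optional complete set of group labels to report.
#' @return a data frame with one row per group.
#' @export
summarize_groups <- function(score_panel, groups, per_sample_fusions = NULL,
                             all_groups = NULL) {
  groups <- groups[score_panel$sample_id]
  lv <- unique(c(sort(unique(as.character(groups[!is.na(groups)]))),
                 all_groups))
  rows <- lapply(lv, function(g) {
    ids <- score_panel$sample_id[!is.na(groups) & groups == g]
    sub <- score_panel[score_panel$sample_id %in% ids, , drop = FALSE]
    n <- nrow(sub)
    mean_or_na <- function(v) if (n == 0) NA_real_ else mean(v)
    data.frame(group = g, n = n,
               mean_tmb = mean_or_na(sub$TMB),
               mean_fusions = if (is.null(per_sample_fusions)) NA_real_
                              else mean_or_na(per_sample_fusions[ids]),
               mean_brs = mean_or_na(sub$BRS),
               mean_tds = mean_or_na(sub$TDS),
               mean_erk = mean_or_na(sub$ERK),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
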