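#!/usr/bin/env Rscript
# Step 5: cluster inference. Tests clusterability with the bootstrapped
# Hopkins statistic (512 replicates; clusterable when mean 1-H < 0.5),
# chooses the number of clusters by bootstrapped multi-index consensus
# (10% of genes per replicate), clusters samples with WPGMA (McQuitty)
# linkage, projects them onto two principal components, flags expression
# outliers, and assigns driver-negative samples to BRAF-like (negative BL)
# or RAS-like (negative RL) groups by their cluster's driver majority.

library(thyroprofiler)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
reps_consensus <- if (length(args) > 1) as.integer(args[[2]]) else 200L

inp <- "results"
em <- read_matrix_tsv(file.path(inp, "expression_matrix.tsv"))$matrix
truth <- read_tsv_stable("results/synthetic/truth.tsv")
driver_status <- setNames(truth$driver_status, truth$sample_id)

outliers <- flag_outliers(em)
core <- setdiff(colnames(em), outliers)
core_mat <- em[, core, drop = FALSE]
message(sprintf("outliers excluded from clustering: %s",
                if (length(outliers)) paste(outliers, collapse = ", ")
                else "none"))

hop <- bootstrapped_clusterability(core_mat, reps = 512,
                                   seed = substream_seed(seed, "hopkins"))
message(sprintf("mean 1-H over %d replicates: %.4f -> %s", hop$reps,
                hop$mean_one_minus_h,
                if (hop$clusterable) "clusterable" else "not clusterable"))

cons <- consensus_cluster_number(core_mat, reps = reps_consensus,
                                 seed = substream_seed(seed, "consensus"))
message(sprintf("consensus over %d evaluations: k = %d (votes %s)",
                cons$n_evaluations, cons$chosen_k,
                paste(sprintf("%s:%d", names(cons$per_k_votes),
                              cons$per_k_votes), collapse = " ")))

wp <- wpgma_cluster(core_mat, cons$chosen_k)
pca <- pca_project(em, 2)
assignments <- assign_negative_classes(wp$labels, driver_status)
message(sprintf("driver-negative assignments: %s",
                paste(sprintf("%s=%s", names(assignments), assignments),
                      collapse = ", ")))

report <- data.frame(
  sample_id = colnames(em),
  cluster = ifelse(colnames(em) %in% core,
                   as.integer(wp$labels[colnames(em)]), NA_integer_),
  assignment = ifelse(colnames(em) %in% names(assignments),
                      assignments[colnames(em)],
                      driver_status[colnames(em)]),
  PC1 = pca[colnames(em), 1], PC2 = pca[colnames(em), 2],
  outlier = colnames(em) %in% outliers,
  stringsAsFactors = FALSE)
write_tsv_stable(report, "results/cluster_report.tsv")
jsonlite::write_json(list(hopkins_mean_one_minus_h = hop$mean_one_minus_h,
                          clusterable = hop$clusterable,
                          per_k_votes = as.list(cons$per_k_votes),
                          chosen_k = cons$chosen_k,
                          outliers = outliers),
                     "results/cluster_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/cluster_report.tsv, results/cluster_summary.json")
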