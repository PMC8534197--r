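#!/usr/bin/env Rscript
# Step 6: the score panel. BRS from Euclidean distances to BRAF/RAS
# centroids fitted on the labelled reference matrix over the 71-gene
# signature, scaled to [-1, 1] (negative = BRAF-like); TDS and ERK as means
# of median-centred log2 FPM over their 16- and 52-gene lists; TMB as
# retained non-synonymous mutations per megabase (50 Mb capture).

library(thyroprofiler)

syn <- "results/synthetic"
em_fpm <- 2^read_matrix_tsv("results/expression_matrix.tsv")$matrix - 1
ref_fpm <- read_matrix_tsv(file.path(syn, "reference_fpm.tsv"))$matrix
ref_labels_df <- read_tsv_stable(file.path(syn, "reference_labels.tsv"))
ref_labels <- setNames(ref_labels_df$label, ref_labels_df$sample_id)
sig <- lapply(c(BRS = "brs71.txt", TDS = "tds16.txt", ERK = "erk52.txt"),
              function(f) read_signature(file.path(syn, f)))
audit <- read_tsv_stable("results/variant_audit.tsv")
retained <- audit[audit$status %in% c("pass", "rescued"), ]
samples <- colnames(em_fpm)

cen <- fit_centroids(ref_fpm, ref_labels, sig$BRS)
panel <- data.frame(
  sample_id = samples,
  BRS = as.numeric(brs_score(em_fpm, cen)[samples]),
  TDS = as.numeric(tds_score(em_fpm, sig$TDS)[samples]),
  ERK = as.numeric(erk_score(em_fpm, sig$ERK)[samples]),
  TMB = as.numeric(tmb(retained, 50, samples = samples)[samples]),
  stringsAsFactors = FALSE)
write_score_panel(panel, "results/score_panel.tsv")

message(sprintf("BRS spans [%.3f, %.3f]; mean TMB %.2f mutations/Mb",
                min(panel$BRS), max(panel$BRS), mean(panel$TMB)))
message("wrote results/score_panel.tsv")
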