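#!/usr/bin/env Rscript
# Step 1: simulate the study cohort under the default conditions -- 30
# tumour samples (14 driver-negative) split between a BRAF-like and a
# RAS-like expression archetype -- plus the mutation-typed reference matrix
# (26 BRAF + 61 RAS) used later for centroid fitting. Writes all inputs the
# downstream steps consume, with ground-truth labels.

library(thyroprofiler)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- cohort_config(seed = seed)
fp <- config_fingerprint(unclass(cc))

cohort <- generate_counts(cc)
variants <- generate_variant_table(cc, cohort$truth)
fusions <- generate_fusion_table(cc, cohort$truth)
reference <- generate_reference_matrix(cc)

write_counts_tsv(cohort$counts, cohort$gene_meta,
                 file.path(out, "counts.tsv"), fp)
write_variants_maf(variants, file.path(out, "variants.maf.tsv"), fp)
write_fusions_tsv(fusions, file.path(out, "fusions.tsv"), fp)
write_truth_tsv(cohort$truth, file.path(out, "truth.tsv"), fp)
write_expression_tsv(reference$fpm, file.path(out, "reference_fpm.tsv"), fp)
write_tsv_stable(data.frame(sample_id = names(reference$labels),
                            label = unname(reference$labels)),
                 file.path(out, "reference_labels.tsv"), fp)
for (sig in c("BRS", "TDS", "ERK")) {
  genes <- signature_genes(cohort$gene_meta, sig)
  writeLines(genes, file.path(out, sprintf("%s%d.txt", tolower(sig),
                                           length(genes))))
}

message(sprintf("cohort: %d samples (%d driver-negative), %d genes",
                ncol(cohort$counts),
                sum(cohort$truth$driver_status == "negative"),
                nrow(cohort$counts)))
message(sprintf("variant calls: %d (%d planted drivers); fusion calls: %d",
                nrow(variants), sum(variants$planted), nrow(fusions)))
message("wrote ", out)
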