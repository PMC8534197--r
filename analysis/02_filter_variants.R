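#!/usr/bin/env Rscript
# Step 2: somatic variant filter chain. Calls with mapping quality below 20
# or a population allele frequency above 0.001 (gnomAD or ABraOM), and
# calls shared with normal thyroid tissue, are removed; removed calls in
# COSMIC oncogenes or tumour suppressors are reimported. The audit table
# keeps every record with its final status and reasons.

library(thyroprofiler)

inp <- "results/synthetic"
out <- "results"
variants <- read_variants_maf(file.path(inp, "variants.maf.tsv"))
normal <- normal_set_from_flags(variants)

res <- run_variant_filter_chain(variants, normal)
write_variant_audit(res$audit, file.path(out, "variant_audit.tsv"))

tab <- table(res$audit$status)
message(sprintf("variants in: %d | pass: %d, rescued: %d, removed: %d",
                nrow(variants), tab[["pass"]], tab[["rescued"]],
                tab[["removed"]]))
message(sprintf("rescued with low mapping quality (audit warning): %d",
                sum(res$audit$low_quality_rescued)))
message("wrote ", file.path(out, "variant_audit.tsv"))
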