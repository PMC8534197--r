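#!/usr/bin/env Rscript
# Step 3: fusion-call filters. Calls need FFPM above 0.1 and both junction
# and spanning read counts above 10; fusions seen in normal thyroid tissue
# are removed. Fusion burden is then summarised per expression archetype.

library(thyroprofiler)

inp <- "results/synthetic"
out <- "results"
fusions <- read_fusions_tsv(file.path(inp, "fusions.tsv"))
truth <- read_tsv_stable(file.path(inp, "truth.tsv"))

filtered <- filter_fusions(fusions)
filtered <- subtract_normal_fusions(filtered, normal_fusion_pairs())
write_fusion_audit(filtered, file.path(out, "fusion_audit.tsv"))

burden <- fusion_burden(filtered, setNames(truth$archetype, truth$sample_id))
write_tsv_stable(burden, file.path(out, "fusion_burden.tsv"))

message(sprintf("fusions in: %d | passing: %d", nrow(fusions),
                sum(filtered$status == "pass")))
for (i in seq_len(nrow(burden)))
  message(sprintf("%s: mean %.2f fusions/sample over %d samples",
                  burden$group[i], burden$mean_fusions[i],
                  burden$n_samples[i]))
message("wrote ", file.path(out, "fusion_audit.tsv"))
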