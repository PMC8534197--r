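# Synthetic cohort generator: determinism, planted structure, count-model
# moments, filter-strata coverage and writer round-trips.

test_that("generators are deterministic under a fixed seed", {
  cc <- small_config(seed = 11)
  a <- generate_counts(cc)
  b <- generate_counts(cc)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_variant_table(cc, a$truth),
                   generate_variant_table(cc, b$truth))
  expect_identical(generate_fusion_table(cc, a$truth),
                   generate_fusion_table(cc, b$truth))
  r1 <- generate_reference_matrix(cc)
  r2 <- generate_reference_matrix(cc)
  expect_identical(r1$fpm, r2$fpm)
  # a different seed changes the draw
  expect_false(identical(a$counts, generate_counts(small_config(seed = 12))$counts))
})

test_that("zero archetype effect leaves signature genes undifferentiated", {
  cc <- small_config(archetype_effect = 0, seed = 3)
  co <- generate_counts(cc)
  lg <- log2(co$counts + 1)
  sig <- co$gene_meta$gene[co$gene_meta$signature != "none"]
  bl <- co$truth$sample_id[co$truth$archetype == "BRAF-like"]
  rl <- co$truth$sample_id[co$truth$archetype == "RAS-like"]
  pvals <- vapply(sig, function(g)
    stats::t.test(lg[g, bl], lg[g, rl])$p.value, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("counts are overdispersed consistently with the NB variance formula", {
  cc <- cohort_config(n_samples = 60L, seed = 5)
  co <- generate_counts(cc)
  rl <- co$truth$sample_id[co$truth$archetype == "RAS-like"]
  sub <- co$counts[co$gene_meta$signature == "none", rl]
  mu <- rowMeans(sub)
  v <- apply(sub, 1, stats::var)
  keep <- mu > 20
  expect_gte(sum(keep), 100)
  # variance exceeds the mean for overdispersed genes
  expect_gte(mean(v[keep] > mu[keep]), 0.9)
  # method of moments: dispersion = (var - mean) / mean^2 near the configured
  # 0.2 (library-size variation adds a small amount)
  disp_hat <- stats::median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_gt(disp_hat, 0.1)
  expect_lt(disp_hat, 0.35)
})

test_that("archetype separation of BRS-like genes meets the planted effect", {
  cc <- cohort_config(n_samples = 60L, archetype_effect = 2, seed = 8)
  co <- generate_counts(cc)
  lg <- log2(co$counts + 1)
  brs <- signature_genes(co$gene_meta, "BRS")
  bl <- co$truth$sample_id[co$truth$archetype == "BRAF-like"]
  rl <- co$truth$sample_id[co$truth$archetype == "RAS-like"]
  diffs <- rowMeans(lg[brs, bl]) - rowMeans(lg[brs, rl])
  expect_gte(mean(abs(diffs)), 1.0)
  # symmetric design: both shift directions occur
  expect_true(any(diffs > 0) && any(diffs < 0))
})

test_that("variant generator covers every filter stratum and plants drivers once", {
  cc <- small_config(seed = 2)
  co <- generate_counts(cc)
  v <- generate_variant_table(cc, co$truth)
  expect_true(any(v$qc < 20))
  expect_true(any(!is.na(v$af_gnomad) & v$af_gnomad > 0.001) ||
                any(!is.na(v$af_abraom) & v$af_abraom > 0.001))
  expect_true(any(v$normal_shared))
  filtered <- v$qc < 20 |
    (!is.na(v$af_gnomad) & v$af_gnomad > 0.001) |
    (!is.na(v$af_abraom) & v$af_abraom > 0.001) | v$normal_shared
  expect_true(any(filtered & v$cosmic_role %in% c("oncogene", "TSG")))
  # planted drivers: one per positive sample, passing quality and rare
  drv <- v[v$planted, ]
  braf_pos <- co$truth$sample_id[co$truth$driver_status == "positive-BRAF"]
  ras_pos <- co$truth$sample_id[co$truth$driver_status == "positive-RAS"]
  expect_identical(sort(drv$sample_id[drv$gene == "BRAF"]), sort(braf_pos))
  expect_identical(sort(drv$sample_id[drv$gene == "NRAS"]), sort(ras_pos))
  expect_true(all(drv$qc >= 20))
  expect_true(all(is.na(drv$af_gnomad) | drv$af_gnomad <= 0.001))
  expect_false(any(drv$sample_id %in%
                     co$truth$sample_id[co$truth$driver_status == "negative"]))
})

test_that("empty background yields only planted driver variants", {
  cc <- small_config(n_background_variants = 0L, fraction_normal_shared = 0,
                     fraction_common_population = 0, seed = 4)
  co <- generate_counts(cc)
  v <- generate_variant_table(cc, co$truth)
  expect_true(all(v$planted))
  expect_true(all(v$gene %in% c("BRAF", "NRAS")))
})

test_that("fusion generator respects rates, plants PAX8-PPARg, and can be silent", {
  cc <- small_config(seed = 6)
  co <- generate_counts(cc)
  f <- generate_fusion_table(cc, co$truth)
  pax8 <- co$truth$sample_id[co$truth$driver_status == "positive-PAX8-PPARg"]
  planted_pax8 <- f[f$gene5 == "PAX8" & f$gene3 == "PPARG", ]
  expect_identical(sort(unique(planted_pax8$sample_id)), sort(pax8))
  expect_true(all(table(planted_pax8$sample_id) == 1))
  # zero rates, no artifacts, no fusion-driven samples -> empty table
  cc0 <- small_config(fusion_rate_by_archetype = c("BRAF-like" = 0,
                                                   "RAS-like" = 0),
                      artifact_fusion_rate = 0, seed = 6)
  truth0 <- data.frame(sample_id = sprintf("S%02d", 1:30),
                       archetype = rep(c("BRAF-like", "RAS-like"), 15),
                       driver_status = "negative", stringsAsFactors = FALSE)
  expect_identical(nrow(generate_fusion_table(cc0, truth0)), 0L)
})

test_that("fusion rates are recovered at large n (Poisson law of large numbers)", {
  cc <- cohort_config(n_samples = 20000L, n_genes = 10L,
                      n_signature_genes = c(BRS = 2L, TDS = 2L, ERK = 2L),
                      archetype_fractions = c("BRAF-like" = 0.5,
                                              "RAS-like" = 0.5),
                      fraction_driver_negative = 1,
                      fusion_rate_by_archetype = c("BRAF-like" = 1.0,
                                                   "RAS-like" = 2.8),
                      artifact_fusion_rate = 0, seed = 9)
  truth <- data.frame(sample_id = sprintf("S%05d", 1:20000),
                      archetype = rep(c("BRAF-like", "RAS-like"),
                                      each = 10000),
                      driver_status = "negative", stringsAsFactors = FALSE)
  f <- generate_fusion_table(cc, truth)
  counts <- table(factor(f$sample_id, levels = truth$sample_id))
  means <- tapply(as.numeric(counts), truth$archetype, mean)
  expect_lt(abs(means[["BRAF-like"]] - 1.0) / 1.0, 0.05)
  expect_lt(abs(means[["RAS-like"]] - 2.8) / 2.8, 0.05)
})

test_that("reference matrix has 26 + 61 labelled samples and errors when degenerate", {
  cc <- small_config(seed = 10)
  ref <- generate_reference_matrix(cc)
  expect_identical(ncol(ref$fpm), 87L)
  expect_identical(sum(ref$labels == "BRAF"), 26L)
  expect_identical(sum(ref$labels == "RAS"), 61L)
  # single-group reference: centroid fitting must error downstream
  cc1 <- small_config(n_reference_braf = 0L, n_reference_ras = 5L, seed = 10)
  ref1 <- generate_reference_matrix(cc1)
  brs <- signature_genes(generate_counts(cc1)$gene_meta, "BRS")
  expect_error(fit_centroids(ref1$fpm, ref1$labels, brs), "BRAF")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_samples = 0), "positive")
  expect_error(cohort_config(archetype_fractions = c("BRAF-like" = 0.6,
                                                     "RAS-like" = 0.6)),
               "sum to 1")
  expect_error(cohort_config(fraction_driver_negative = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(dispersion = -1), "dispersion")
})

test_that("table writers and readers round-trip", {
  cc <- small_config(seed = 13)
  co <- generate_counts(cc)
  v <- generate_variant_table(cc, co$truth)
  f <- generate_fusion_table(cc, co$truth)
  dir <- withr::local_tempdir()
  write_counts_tsv(co$counts, co$gene_meta, file.path(dir, "counts.tsv"),
                   fingerprint = "abc")
  cm <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  expect_equal(unname(cm$matrix), unname(co$counts))
  expect_identical(cm$gene_meta$biotype, co$gene_meta$biotype)
  write_variants_maf(v, file.path(dir, "variants.maf.tsv"))
  v2 <- read_variants_maf(file.path(dir, "variants.maf.tsv"))
  expect_equal(v2$qc, round(v$qc, 10), tolerance = 1e-5)
  expect_identical(v2$gene, v$gene)
  expect_identical(v2$normal_shared, v$normal_shared)
  write_fusions_tsv(f, file.path(dir, "fusions.tsv"))
  f2 <- read_fusions_tsv(file.path(dir, "fusions.tsv"))
  expect_identical(f2$gene5, f$gene5)
  expect_identical(f2$junction_reads, f$junction_reads)
  expect_equal(f2$ffpm, f$ffpm, tolerance = 1e-5)
})
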