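# Expression-matrix construction: prevalence boundaries, pseudogene
# exclusion, COSMIC rescue set algebra, median-of-ratios size factors (with
# an independent cross-check), FPM limit cases and the log transform.

toy_meta <- function(genes, biotype = "protein_coding", cosmic = "none") {
  data.frame(gene = genes, biotype = rep_len(biotype, length(genes)),
             cosmic_role = rep_len(cosmic, length(genes)),
             stringsAsFactors = FALSE)
}

test_that("prevalence filter honours its boundaries", {
  counts <- matrix(11L, nrow = 3, ncol = 30,
                   dimnames = list(c("g1", "g2", "g3"), sprintf("S%02d", 1:30)))
  counts["g1", 28:30] <- 0L   # count > 10 in exactly 27/30 = 90% -> retained
  counts["g2", ] <- 10L       # never strictly above 10 -> dropped
  expect_identical(filter_genes(counts), c("g1", "g3"))
  # min_fraction = 0 retains everything
  expect_identical(filter_genes(counts, min_fraction = 0),
                   c("g1", "g2", "g3"))
  expect_error(filter_genes(counts[0, , drop = FALSE]), "empty")
})

test_that("pseudogene exclusion is substring- and case-insensitive", {
  meta <- toy_meta(c("a", "b", "c", "d"),
                   biotype = c("processed_pseudogene", "protein_coding",
                               "PSEUDOGENE", "transcribed_pseudogene"))
  expect_identical(exclude_pseudogenes(c("a", "b", "c", "d"), meta), "b")
  expect_error(exclude_pseudogenes(c("a", "zz"), meta), "missing biotype")
})

test_that("COSMIC rescue overrides prevalence and pseudogene exclusion", {
  meta <- toy_meta(c("a", "b", "c"), cosmic = c("oncogene", "none", "none"))
  out <- rescue_cancer_genes(retained = "b", gene_meta = meta)
  expect_identical(out$genes, c("a", "b"))
  expect_identical(out$provenance$reason[out$provenance$gene == "a"],
                   "cosmic_rescue")
  # a retained COSMIC gene keeps prevalence provenance, no double entry
  meta2 <- toy_meta(c("a", "b"), cosmic = c("TSG", "none"))
  out2 <- rescue_cancer_genes(retained = c("a", "b"), gene_meta = meta2)
  expect_identical(out2$provenance$reason, c("prevalence", "prevalence"))
  expect_identical(anyDuplicated(out2$genes), 0L)
})

test_that("final gene set equals brute-force set algebra on random inputs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 60
      genes <- sprintf("g%02d", 1:n)
      counts <- matrix(rpois(n * 10, 15), nrow = n,
                       dimnames = list(genes, sprintf("S%02d", 1:10)))
      meta <- toy_meta(genes,
                       biotype = sample(c("protein_coding", "x_pseudogene"),
                                        n, TRUE, prob = c(0.8, 0.2)),
                       cosmic = sample(c("none", "oncogene", "TSG"),
                                       n, TRUE, prob = c(0.8, 0.1, 0.1)))
    })
    prevalence <- genes[rowSums(counts > 10) >= ceiling(0.9 * 10)]
    pseudo <- genes[grepl("pseudogene", meta$biotype, ignore.case = TRUE)]
    cosmic <- genes[meta$cosmic_role != "none"]
    expected <- genes[genes %in% union(setdiff(prevalence, pseudo), cosmic)]
    got <- rescue_cancer_genes(exclude_pseudogenes(filter_genes(counts),
                                                   meta), meta)$genes
    expect_identical(got, expected)
  }
})

test_that("median-of-ratios size factors match hand-computed ratios", {
  # identical columns -> all factors 1; single sample -> 1
  m <- matrix(c(5L, 20L, 100L), nrow = 3, ncol = 4,
              dimnames = list(c("a", "b", "c"), sprintf("S%d", 1:4)))
  expect_equal(unname(size_factors_median_of_ratios(m)), rep(1, 4))
  expect_equal(unname(size_factors_median_of_ratios(m[, 1, drop = FALSE])), 1)
  # 3-gene toy with column B = 2 x column A: geometric means are
  # sqrt(2) * colA, so factors are (1/sqrt(2), sqrt(2)) -- proportional to
  # (1, 2) with unit geometric mean
  toy <- cbind(A = c(10, 20, 40), B = c(20, 40, 80))
  sf <- size_factors_median_of_ratios(toy)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(sf[["B"]] / sf[["A"]], 2)
  # no gene positive everywhere -> informative error
  z <- cbind(c(0, 5), c(5, 0))
  rownames(z) <- c("a", "b")
  expect_error(size_factors_median_of_ratios(z), "pseudo-reference")
})

test_that("scaling one sample scales its relative size factor by the same constant", {
  withr::with_seed(31, {
    m <- matrix(rpois(50 * 6, 30) + 1L, nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("S%d", 1:6)))
  })
  sf <- size_factors_median_of_ratios(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  sf2 <- size_factors_median_of_ratios(m2)
  # equivariance holds for factor ratios (the overall scale is pinned to a
  # unit geometric mean)
  expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), 5, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("size factors agree with the reference count-model implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(32, {
    m <- matrix(rnbinom(200 * 8, mu = 50, size = 5) + 1L, nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("S%d", 1:8)))
  })
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("FPM reduces to CPM with unit factors and is invariant to depth doubling", {
  m <- matrix(c(100L, 300L, 600L, 200L, 600L, 1200L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  # unit factors, equal library sizes: columns sum to 1e6
  eq <- cbind(S1 = m[, 1], S2 = m[, 1])
  fpm_eq <- fpm_normalize(eq, c(1, 1))
  expect_equal(unname(colSums(fpm_eq)), c(1e6, 1e6))
  # doubling every count of one sample (factors recomputed) leaves FPM
  # unchanged: the factor and the robust library size absorb the depth shift
  sf <- size_factors_median_of_ratios(m)
  base <- fpm_normalize(m, sf)
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf2 <- size_factors_median_of_ratios(m2)
  expect_equal(fpm_normalize(m2, sf2), base, tolerance = 1e-12)
  # zero counts stay zero; zero factors and empty matrices error
  with_zero <- rbind(g0 = c(0, 0), g1 = c(100, 200))
  expect_equal(unname(fpm_normalize(with_zero, c(1, 1))["g0", ]), c(0, 0))
  expect_error(fpm_normalize(m, c(0, 1)), "size factor")
  expect_error(fpm_normalize(rbind(c(0, 0)), c(1, 1)), "no reads")
})

test_that("log transform maps known values and preserves ordering", {
  expect_equal(log_transform(rbind(c(0, 1, 3)))[1, ], c(0, 1, 2))
  expect_error(log_transform(rbind(c(-1, 2))), "non-negative")
  withr::with_seed(33, x <- matrix(runif(30, 0, 100), nrow = 5))
  expect_identical(order(log_transform(x)[, 1]), order(x[, 1]))
})

test_that("build_expression_matrix composes the stages with provenance", {
  cc <- small_config(seed = 17)
  co <- generate_counts(cc)
  em <- build_expression_matrix(co$counts, co$gene_meta)
  expect_s3_class(em, "expression_matrix")
  expect_true(all(em$log2fpm >= 0))
  expect_true(all(em$size_factors > 0))
  expect_identical(rownames(em$log2fpm), em$genes)
  expect_identical(sort(unique(em$provenance$reason)),
                   c("cosmic_rescue", "prevalence"))
  # pseudogenes absent unless rescued
  meta <- co$gene_meta
  pseudo_not_cosmic <- meta$gene[grepl("pseudogene", meta$biotype) &
                                   meta$cosmic_role == "none"]
  expect_identical(intersect(em$genes, pseudo_not_cosmic), character(0))
})
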