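# Synthetic cohort generator: negative-binomial count matrices with two
# expression archetypes (BRAF-like / RAS-like), planted driver mutations and
# fusions, and background variant/fusion noise spanning every filter stratum.
# Ground truth is returned alongside so every downstream stage is testable
# without patient data.

#' Configuration for a synthetic thyroid-tumour cohort
#'
#' Defaults emulate the discovery-cohort conditions the pipeline was designed
#' around: 30 samples of which 14 are driver-negative, a small BRAF-like
#' archetype (30%) and a larger RAS-like archetype (70%), signature gene sets
#' of 71 (BRS-like), 16 (TDS-like) and 52 (ERK-like) genes shifted by
#' `archetype_effect` log2 units between archetypes, negative-binomial counts,
#' and genuine fusion rates of 1.0 (BRAF-like) and 2.8 (RAS-like) fusions per
#' sample.
#'
#' @param n_samples number of tumour samples (default 30).
#' @param n_genes size of the gene universe (default 2000).
#' @param n_signature_genes named integer vector: genes per signature
#'   (defaults `c(BRS = 71, TDS = 16, ERK = 52)`).
#' @param archetype_fractions named proportions over
#'   `c("BRAF-like", "RAS-like")`; must sum to 1.
#' @param fraction_driver_negative proportion of samples without a planted
#'   driver (default 14/30).
#' @param archetype_effect log2 fold-shift magnitude applied to signature
#'   genes between archetypes (default 2.0).
#' @param dispersion negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2); 0 gives Poisson counts. Default 0.2.
#' @param library_size_range range (pair) of target per-sample library sizes.
#' @param n_background_variants passenger variant calls per sample
#'   (default 300, calibrated so the retained non-synonymous burden matches a
#'   mutation burden near 3.8 mutations/Mb at a 50 Mb capture).
#' @param fraction_low_quality,fraction_normal_shared,fraction_common_population
#'   per-record probabilities of the three filterable strata (defaults 0.1).
#' @param fraction_pseudogene fraction of genes given a pseudogene biotype.
#' @param fraction_cosmic fraction of genes catalogued with a COSMIC role.
#' @param fusion_rate_by_archetype named mean counts of genuine (filter-
#'   surviving) fusions per sample by archetype.
#' @param artifact_fusion_rate mean count per sample of artifact fusions whose
#'   support statistics straddle the filter thresholds or that match the
#'   normal-tissue blacklist.
#' @param n_reference_braf,n_reference_ras labelled reference-matrix sizes for
#'   centroid fitting (defaults 26 and 61).
#' @param seed master seed; every generator draws from a sub-stream of it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 30L,
                          n_genes = 2000L,
                          n_signature_genes = c(BRS = 71L, TDS = 16L, ERK = 52L),
                          archetype_fractions = c("BRAF-like" = 0.3,
                                                  "RAS-like" = 0.7),
                          fraction_driver_negative = 14 / 30,
                          archetype_effect = 2.0,
                          dispersion = 0.2,
                          library_size_range = c(8e5, 1.2e6),
                          n_background_variants = 300L,
                          fraction_low_quality = 0.1,
                          fraction_normal_shared = 0.1,
                          fraction_common_population = 0.1,
                          fraction_pseudogene = 0.1,
                          fraction_cosmic = 0.05,
                          fusion_rate_by_archetype = c("BRAF-like" = 1.0,
                                                       "RAS-like" = 2.8),
                          artifact_fusion_rate = 1.0,
                          n_reference_braf = 26L,
                          n_reference_ras = 61L,
                          seed = 1L) {
  storage.mode(n_signature_genes) <- "integer"
  storage.mode(archetype_fractions) <- "double"
  storage.mode(fusion_rate_by_archetype) <- "double"
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_signature_genes = n_signature_genes,
              archetype_fractions = archetype_fractions,
              fraction_driver_negative = as.numeric(fraction_driver_negative),
              archetype_effect = as.numeric(archetype_effect),
              dispersion = as.numeric(dispersion),
              library_size_range = as.numeric(library_size_range),
              n_background_variants = as.integer(n_background_variants),
              fraction_low_quality = as.numeric(fraction_low_quality),
              fraction_normal_shared = as.numeric(fraction_normal_shared),
              fraction_common_population = as.numeric(fraction_common_population),
              fraction_pseudogene = as.numeric(fraction_pseudogene),
              fraction_cosmic = as.numeric(fraction_cosmic),
              fusion_rate_by_archetype = fusion_rate_by_archetype,
              artifact_fusion_rate = as.numeric(artifact_fusion_rate),
              n_reference_braf = as.integer(n_reference_braf),
              n_reference_ras = as.integer(n_reference_ras),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- c("cohort_config", "list")
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 1L || cfg$n_genes < 1L)
    stopf("configuration error: dimensions must be positive (n_samples=%d, n_genes=%d)",
          cfg$n_samples, cfg$n_genes)
  if (abs(sum(cfg$archetype_fractions) - 1) > 1e-8)
    stopf("configuration error: archetype_fractions must sum to 1")
  if (!all(names(cfg$archetype_fractions) %in% c("BRAF-like", "RAS-like")))
    stopf("configuration error: archetypes must be 'BRAF-like' and 'RAS-like'")
  props <- c(cfg$fraction_driver_negative, cfg$fraction_low_quality,
             cfg$fraction_normal_shared, cfg$fraction_common_population,
             cfg$fraction_pseudogene, cfg$fraction_cosmic,
             cfg$archetype_fractions)
  if (any(props < 0 | props > 1))
    stopf("configuration error: all proportions must lie in [0, 1]")
  if (sum(cfg$n_signature_genes) > cfg$n_genes)
    stopf("configuration error: signature genes exceed the gene universe")
  if (cfg$n_background_variants < 0L || any(cfg$fusion_rate_by_archetype < 0))
    stopf("configuration error: counts and rates must be nonnegative")
  if (cfg$dispersion < 0)
    stopf("configuration error: dispersion must be nonnegative")
  invisible(cfg)
}

# Gene universe shared by the cohort and the labelled reference matrix: base
# means (log-normal), disjoint signature memberships with symmetric shift
# directions (half of each signature up in each archetype), biotypes and
# COSMIC roles. Deterministic given the config's seed.
gene_universe <- function(config) {
  with_seed(substream_seed(config$seed, "genes"), {
    n <- config$n_genes
    gene <- sprintf("G%04d", seq_len(n))
    base_mean <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.25)
    signature <- rep("none", n)
    direction <- rep(0L, n)
    idx_pool <- sample.int(n, sum(config$n_signature_genes))
    offset <- 0L
    for (sig in names(config$n_signature_genes)) {
      k <- config$n_signature_genes[[sig]]
      idx <- idx_pool[offset + seq_len(k)]
      offset <- offset + k
      signature[idx] <- sig
      # symmetric: first half up in BRAF-like, second half up in RAS-like
      direction[idx] <- rep(c(1L, -1L), length.out = k)
    }
    # signature genes model well-expressed markers: floor their base means so
    # they survive the prevalence filter even when down-shifted
    base_mean[signature != "none"] <- pmax(base_mean[signature != "none"], 100)
    biotype <- ifelse(stats::runif(n) < config$fraction_pseudogene,
                      "processed_pseudogene", "protein_coding")
    # signature and driver genes must survive the pseudogene exclusion
    biotype[signature != "none"] <- "protein_coding"
    cosmic_role <- ifelse(stats::runif(n) < config$fraction_cosmic,
                          sample(c("oncogene", "TSG"), n, replace = TRUE),
                          "none")
    # canonical driver genes, placed on non-signature slots
    drivers <- c("BRAF", "NRAS", "PAX8", "PPARG")
    free <- which(signature == "none")[1:4]
    gene[free] <- drivers
    biotype[free] <- "protein_coding"
    cosmic_role[free] <- c("oncogene", "oncogene", "oncogene", "TSG")
    data.frame(gene = gene, base_mean = base_mean, biotype = biotype,
               cosmic_role = cosmic_role, signature = signature,
               direction = direction, stringsAsFactors = FALSE)
  })
}

# Archetypes and driver statuses for one cohort. Negatives are allocated
# proportionally within archetypes (capped so each archetype keeps at least
# one driver-positive member, mirroring the mutation-positive comparison
# groups that anchor each expression cluster).
assign_truth <- function(config) {
  with_seed(substream_seed(config$seed, "truth"), {
    n <- config$n_samples
    sample_id <- sprintf("S%02d", seq_len(n))
    n_bl <- round(config$archetype_fractions[["BRAF-like"]] * n)
    n_bl <- max(min(n_bl, n), 0)
    archetype <- sample(c(rep("BRAF-like", n_bl), rep("RAS-like", n - n_bl)))
    n_neg <- round(config$fraction_driver_negative * n)
    driver_status <- rep("", n)
    for (arch in unique(archetype)) {
      idx <- which(archetype == arch)
      share <- round(n_neg * length(idx) / n)
      if (length(idx) > 1) share <- min(share, length(idx) - 1L)
      share <- min(share, length(idx))
      neg <- if (share > 0) sample(idx, share) else integer(0)
      driver_status[idx] <- "positive"
      driver_status[neg] <- "negative"
    }
    pos_bl <- which(archetype == "BRAF-like" & driver_status == "positive")
    pos_rl <- which(archetype == "RAS-like" & driver_status == "positive")
    driver_status[pos_bl] <- "positive-BRAF"
    # RAS-like positives split between RAS point mutations and PAX8-PPARg
    # fusions at the 11:3 ratio of the motivating cohort
    is_pax8 <- stats::runif(length(pos_rl)) < 3 / 14
    driver_status[pos_rl] <- ifelse(is_pax8, "positive-PAX8-PPARg",
                                    "positive-RAS")
    data.frame(sample_id = sample_id, archetype = archetype,
               driver_status = driver_status, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic count matrix with planted archetype structure
#'
#' Counts are negative binomial with log-normal gene base means. Signature
#' genes are shifted by `archetype_effect` log2 units between archetypes,
#' symmetrically (half of each signature up in BRAF-like samples, half up in
#' RAS-like), so both signs of the BRAF-RAS score are exercised.
#'
#' @param config a [cohort_config()].
#' @return a list with `counts` (genes x samples integer matrix),
#'   `gene_meta` (gene, biotype, cosmic_role, signature, direction) and
#'   `truth` (sample_id, archetype, driver_status).
#' @export
generate_counts <- function(config) {
  validate_cohort_config(config)
  genes <- gene_universe(config)
  truth <- assign_truth(config)
  counts <- simulate_nb_counts(config, genes, truth$archetype, "counts")
  colnames(counts) <- truth$sample_id
  list(counts = counts,
       gene_meta = genes[, c("gene", "biotype", "cosmic_role",
                             "signature", "direction")],
       truth = truth)
}

simulate_nb_counts <- function(config, genes, archetypes, stream) {
  with_seed(substream_seed(config$seed, stream), {
    n_genes <- nrow(genes)
    n_samples <- length(archetypes)
    lib <- stats::runif(n_samples, config$library_size_range[1],
                        config$library_size_range[2])
    depth <- lib / 1e6
    half <- config$archetype_effect / 2
    counts <- matrix(0L, nrow = n_genes, ncol = n_samples,
                     dimnames = list(genes$gene, NULL))
    for (j in seq_len(n_samples)) {
      arch_sign <- if (archetypes[j] == "BRAF-like") 1 else -1
      mu <- genes$base_mean * 2^(genes$direction * arch_sign * half) * depth[j]
      counts[, j] <- if (config$dispersion > 0)
        stats::rnbinom(n_genes, mu = mu, size = 1 / config$dispersion)
      else stats::rpois(n_genes, mu)
    }
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Extract the gene list of one synthetic signature
#'
#' @param gene_meta the `gene_meta` table from [generate_counts()].
#' @param name one of `"BRS"`, `"TDS"`, `"ERK"`.
#' @return character vector of gene symbols.
#' @export
signature_genes <- function(gene_meta, name) {
  gene_meta$gene[gene_meta$signature == name]
}

variant_classes <- c("missense", "silent", "nonsense", "frameshift_indel",
                     "inframe_indel", "splice", "other")
variant_class_probs <- c(0.60, 0.15, 0.05, 0.08, 0.05, 0.04, 0.03)

#' Generate an annotated somatic variant table for a synthetic cohort
#'
#' Background (passenger) records span every filter stratum: a fraction with
#' mapping quality below 20, a fraction with population allele frequency above
#' 0.001 in gnomAD or ABraOM, a fraction shared with normal tissue, and
#' COSMIC-gene records planted inside otherwise-filtered strata so the rescue
#' path is exercised. Planted driver variants (BRAF V600E, NRAS Q61R) have
#' passing quality and rare frequency.
#'
#' @param config a [cohort_config()].
#' @param truth the truth table from [generate_counts()].
#' @return a data frame of variant records with `status = "pass"` and empty
#'   `removal_reasons` (filters assign provenance); the planted driver rows
#'   are marked in the `planted` column.
#' @export
generate_variant_table <- function(config, truth) {
  if (nrow(truth) != config$n_samples)
    stopf("truth table inconsistent with config (%d vs %d samples)",
          nrow(truth), config$n_samples)
  genes <- gene_universe(config)
  with_seed(substream_seed(config$seed, "variants"), {
    rows <- vector("list", nrow(truth) + 1L)
    for (i in seq_len(nrow(truth))) {
      nb <- config$n_background_variants
      if (nb == 0) { rows[[i]] <- NULL; next }
      gidx <- sample.int(nrow(genes), nb, replace = TRUE)
      low_q <- stats::runif(nb) < config$fraction_low_quality
      common <- stats::runif(nb) < config$fraction_common_population
      shared <- stats::runif(nb) < config$fraction_normal_shared
      qc <- ifelse(low_q, stats::runif(nb, 2, 19.5), stats::runif(nb, 25, 60))
      af_g <- ifelse(common & stats::runif(nb) < 0.7,
                     stats::runif(nb, 0.0015, 0.05), NA_real_)
      af_a <- ifelse(common & is.na(af_g),
                     stats::runif(nb, 0.0015, 0.05), NA_real_)
      # rare records: half carry a tiny measured frequency, half are absent
      # from both databases
      rare_meas <- !common & stats::runif(nb) < 0.5
      af_g[rare_meas] <- stats::runif(sum(rare_meas), 0, 5e-4)
      rows[[i]] <- data.frame(
        sample_id = truth$sample_id[i],
        chrom = as.character(sample.int(22L, nb, replace = TRUE)),
        pos = sample.int(2e8L, nb, replace = TRUE),
        ref = sample(c("A", "C", "G", "T"), nb, replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), nb, replace = TRUE),
        gene = genes$gene[gidx],
        variant_class = sample(variant_classes, nb, replace = TRUE,
                               prob = variant_class_probs),
        qc = qc, af_gnomad = af_g, af_abraom = af_a,
        cosmic_role = genes$cosmic_role[gidx],
        normal_shared = shared, planted = FALSE,
        stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, rows)
    if (!is.null(bg) && nrow(bg) >= 4) {
      # guarantee the generator contract: one record per filter stratum and
      # one COSMIC-gene record inside a filtered stratum
      bg$qc[1] <- 15; bg$cosmic_role[1] <- "none"
      bg$af_gnomad[2] <- 0.01; bg$cosmic_role[2] <- "none"
      bg$normal_shared[3] <- TRUE; bg$cosmic_role[3] <- "none"
      bg$af_gnomad[4] <- 0.01; bg$qc[4] <- 50
      bg$normal_shared[4] <- FALSE; bg$cosmic_role[4] <- "TSG"
    }
    drv <- planted_driver_variants(truth)
    out <- rbind(bg, drv)
    if (is.null(out)) out <- drv
    out$status <- rep("pass", nrow(out))
    out$removal_reasons <- rep("", nrow(out))
    rownames(out) <- NULL
    out
  })
}

planted_driver_variants <- function(truth) {
  braf <- truth$sample_id[truth$driver_status == "positive-BRAF"]
  ras <- truth$sample_id[truth$driver_status == "positive-RAS"]
  mk <- function(ids, chrom, pos, ref, alt, gene) {
    if (length(ids) == 0) return(NULL)
    data.frame(sample_id = ids, chrom = chrom, pos = pos, ref = ref,
               alt = alt, gene = gene, variant_class = "missense",
               qc = 60, af_gnomad = NA_real_, af_abraom = NA_real_,
               cosmic_role = "oncogene", normal_shared = FALSE,
               planted = TRUE, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(braf, "7", 140453136L, "A", "T", "BRAF"),
               mk(ras, "1", 115256529L, "T", "C", "NRAS"))
  if (is.null(out))
    out <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      variant_class = character(0), qc = numeric(0),
                      af_gnomad = numeric(0), af_abraom = numeric(0),
                      cosmic_role = character(0), normal_shared = logical(0),
                      planted = logical(0), stringsAsFactors = FALSE)
  out
}

#' Synthetic normal-tissue fusion blacklist
#'
#' The fixed pool of gene pairs the generator uses for normal-tissue
#' artifact fusions; passing it to [subtract_normal_fusions()] plays the
#' role a normal-tissue fusion set plays on real data.
#' @return a data frame with `gene5` and `gene3` columns.
#' @export
normal_fusion_pairs <- function() {
  data.frame(gene5 = sprintf("NORM%02dA", 1:20),
             gene3 = sprintf("NORM%02dB", 1:20),
             stringsAsFactors = FALSE)
}

#' Generate a fusion-call table for a synthetic cohort
#'
#' Genuine fusions per sample are Poisson with an archetype-dependent mean and
#' carry passing support (junction and spanning reads above 10, FFPM above
#' 0.1). Artifact fusions are added at `artifact_fusion_rate` per sample with
#' shifted-geometric support statistics that straddle the filter thresholds,
#' and a subset drawn from the normal-tissue blacklist pool. PAX8-PPARg
#' driver fusions are planted in the corresponding positive samples.
#'
#' @param config a [cohort_config()].
#' @param truth the truth table from [generate_counts()].
#' @return a data frame of fusion records (`planted` marks genuine fusions).
#' @export
generate_fusion_table <- function(config, truth) {
  if (nrow(truth) != config$n_samples)
    stopf("truth table inconsistent with config")
  with_seed(substream_seed(config$seed, "fusions"), {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      sid <- truth$sample_id[i]
      rate <- config$fusion_rate_by_archetype[[truth$archetype[i]]]
      n_real <- stats::rpois(1, rate)
      is_pax8 <- truth$driver_status[i] == "positive-PAX8-PPARg"
      if (n_real > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid,
          gene5 = sprintf("FUS%03dA", sample.int(999L, n_real, replace = TRUE)),
          gene3 = sprintf("FUS%03dB", sample.int(999L, n_real, replace = TRUE)),
          junction_reads = 11L + stats::rgeom(n_real, 0.08),
          spanning_frags = 11L + stats::rgeom(n_real, 0.08),
          ffpm = 0.1 + stats::rexp(n_real, 1 / 0.6),
          planted = TRUE, stringsAsFactors = FALSE)
      }
      if (is_pax8) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene5 = "PAX8", gene3 = "PPARG",
          junction_reads = 11L + stats::rgeom(1, 0.05),
          spanning_frags = 11L + stats::rgeom(1, 0.05),
          ffpm = 0.2 + stats::rexp(1, 1 / 0.8),
          planted = TRUE, stringsAsFactors = FALSE)
      }
      n_art <- stats::rpois(1, config$artifact_fusion_rate)
      if (n_art > 0) {
        from_blacklist <- stats::runif(n_art) < 0.5
        pool <- normal_fusion_pairs()
        pick <- sample.int(nrow(pool), n_art, replace = TRUE)
        g5 <- ifelse(from_blacklist, pool$gene5[pick],
                     sprintf("ART%03dA", sample.int(999L, n_art, replace = TRUE)))
        g3 <- ifelse(from_blacklist, pool$gene3[pick],
                     sprintf("ART%03dB", sample.int(999L, n_art, replace = TRUE)))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene5 = g5, gene3 = g3,
          # shifted geometric around the threshold so boundaries occur
          junction_reads = 5L + stats::rgeom(n_art, 0.15),
          spanning_frags = 5L + stats::rgeom(n_art, 0.15),
          ffpm = stats::rexp(n_art, 1 / 0.12),
          planted = FALSE, stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(0), gene5 = character(0),
                 gene3 = character(0), junction_reads = integer(0),
                 spanning_frags = integer(0), ffpm = numeric(0),
                 planted = logical(0), stringsAsFactors = FALSE)
    out$status <- rep("pass", nrow(out))
    out$removal_reasons <- rep("", nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Generate a labelled reference expression matrix for centroid fitting
#'
#' Emulates an external reference cohort of mutation-typed tumours (by
#' default 26 BRAF-mutant and 61 RAS-mutant samples) drawn from the same gene
#' universe as the study cohort, FPM-normalised with median-of-ratios size
#' factors.
#'
#' @param config a [cohort_config()].
#' @return a list with `fpm` (genes x samples FPM matrix), `log2fpm`,
#'   `labels` (named character vector, `"BRAF"` / `"RAS"`), and `gene_meta`.
#' @export
generate_reference_matrix <- function(config) {
  validate_cohort_config(config)
  n_b <- config$n_reference_braf
  n_r <- config$n_reference_ras
  if (n_b + n_r < 1L) stopf("reference matrix needs at least one sample")
  genes <- gene_universe(config)
  archetypes <- c(rep("BRAF-like", n_b), rep("RAS-like", n_r))
  counts <- simulate_nb_counts(config, genes, archetypes, "reference")
  colnames(counts) <- sprintf("REF%02d", seq_along(archetypes))
  sf <- size_factors_median_of_ratios(counts)
  fpm <- fpm_normalize(counts, sf)
  labels <- stats::setNames(ifelse(archetypes == "BRAF-like", "BRAF", "RAS"),
                            colnames(counts))
  list(fpm = fpm, log2fpm = log_transform(fpm), labels = labels,
       gene_meta = genes[, c("gene", "biotype", "cosmic_role",
                             "signature", "direction")])
}

# ---- writers ----------------------------------------------------------------

#' Write a synthetic count matrix as TSV (genes as rows, metadata columns)
#' @param counts genes x samples integer matrix.
#' @param gene_meta gene metadata with `biotype` and `cosmic_role`.
#' @param path output file.
#' @param fingerprint optional config fingerprint for the header.
#' @export
write_counts_tsv <- function(counts, gene_meta, path, fingerprint = NULL) {
  stopifnot(identical(rownames(counts), gene_meta$gene))
  df <- data.frame(gene = rownames(counts), biotype = gene_meta$biotype,
                   cosmic_role = gene_meta$cosmic_role,
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(df, path, fingerprint)
}

#' Write variant records as a MAF-style TSV
#' @param records variant record data frame.
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_variants_maf <- function(records, path, fingerprint = NULL) {
  df <- data.frame(Tumor_Sample_Barcode = records$sample_id,
                   Hugo_Symbol = records$gene,
                   Chromosome = records$chrom,
                   Start_Position = records$pos,
                   Reference_Allele = records$ref,
                   Tumor_Seq_Allele2 = records$alt,
                   Variant_Classification = records$variant_class,
                   QC = records$qc,
                   AF_gnomAD = records$af_gnomad,
                   AF_ABraOM = records$af_abraom,
                   cosmic_role = records$cosmic_role,
                   normal_shared = records$normal_shared,
                   stringsAsFactors = FALSE)
  write_tsv_stable(df, path, fingerprint)
}

#' Read a MAF-style TSV into the variant-record layout
#' @param path file to read.
#' @return a variant record data frame with fresh `pass` statuses.
#' @export
read_variants_maf <- function(path) {
  df <- read_tsv_stable(path)
  out <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
                    chrom = as.character(df$Chromosome),
                    pos = as.integer(df$Start_Position),
                    ref = as.character(df$Reference_Allele),
                    alt = as.character(df$Tumor_Seq_Allele2),
                    gene = as.character(df$Hugo_Symbol),
                    variant_class = as.character(df$Variant_Classification),
                    qc = as.numeric(df$QC),
                    af_gnomad = as.numeric(df$AF_gnomAD),
                    af_abraom = as.numeric(df$AF_ABraOM),
                    cosmic_role = as.character(df$cosmic_role),
                    stringsAsFactors = FALSE)
  if ("normal_shared" %in% names(df))
    out$normal_shared <- as.logical(df$normal_shared)
  out$status <- "pass"
  out$removal_reasons <- ""
  out
}

#' Write fusion records in STAR-Fusion-style columns
#' @param records fusion record data frame.
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_fusions_tsv <- function(records, path, fingerprint = NULL) {
  df <- data.frame(sample_id = records$sample_id,
                   "#FusionName" = paste0(records$gene5, "--", records$gene3),
                   LeftGene = records$gene5, RightGene = records$gene3,
                   JunctionReadCount = records$junction_reads,
                   SpanningFragCount = records$spanning_frags,
                   FFPM = records$ffpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(df, path, fingerprint)
}

#' Read a STAR-Fusion-style TSV
#'
#' Accepts either a cohort file with a `sample_id` column or a single-sample
#' STAR-Fusion file (supply `sample_id`). Gene pairs are taken from
#' `#FusionName` (`GENE5--GENE3`).
#' @param path file to read.
#' @param sample_id sample identifier for single-sample files.
#' @return a fusion record data frame with fresh `pass` statuses.
#' @export
read_fusions_tsv <- function(path, sample_id = NULL) {
  df <- read_tsv_stable(path)
  nm <- names(df)
  fuse_col <- nm[nm %in% c("#FusionName", "X.FusionName", "FusionName")][1]
  pairs <- strsplit(as.character(df[[fuse_col]]), "--", fixed = TRUE)
  sid <- if ("sample_id" %in% nm) as.character(df$sample_id)
         else rep(sample_id %||% stopf("sample_id required for single-sample fusion files"),
                  nrow(df))
  data.frame(sample_id = sid,
             gene5 = vapply(pairs, `[`, character(1), 1),
             gene3 = vapply(pairs, `[`, character(1), 2),
             junction_reads = as.integer(df$JunctionReadCount),
             spanning_frags = as.integer(df$SpanningFragCount),
             ffpm = as.numeric(df$FFPM),
             status = "pass", removal_reasons = "",
             stringsAsFactors = FALSE)
}

#' Write ground-truth labels as TSV
#' @param truth truth table from [generate_counts()].
#' @param path output file.
#' @param fingerprint optional config fingerprint.
#' @export
write_truth_tsv <- function(truth, path, fingerprint = NULL) {
  write_tsv_stable(truth[, c("sample_id", "archetype", "driver_status")],
                   path, fingerprint)
}
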