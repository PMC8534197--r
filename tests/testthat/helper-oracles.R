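# Independent reference implementations used only to check the package:
# a naive O(n^3) WPGMA agglomerator, brute-force per-record filter
# predicates, and small record constructors for fixtures.

# Naive WPGMA: scan all active pairs each step, merge the closest (ties to
# the smallest index pair), update distances with the unweighted average of
# the two children. Returns merge heights and the partition at every k.
naive_wpgma <- function(dm) {
  n <- nrow(dm)
  d <- as.matrix(dm)
  active <- seq_len(n)
  labels <- seq_len(n)            # current cluster id per sample
  heights <- numeric(n - 1)
  partitions <- vector("list", n) # partitions[[k]] = labels at k clusters
  partitions[[n]] <- labels
  next_id <- n
  for (step in seq_len(n - 1)) {
    best_i <- NA; best_j <- NA; best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]; j <- active[b]
        if (d[i, j] < best_d - 1e-12) {
          best_d <- d[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    heights[step] <- best_d
    next_id <- next_id + 1L
    d <- rbind(cbind(d, NA), NA)
    for (x in active) {
      if (x == best_i || x == best_j) next
      d[next_id, x] <- d[x, next_id] <- (d[best_i, x] + d[best_j, x]) / 2
    }
    d[next_id, next_id] <- 0
    active <- c(setdiff(active, c(best_i, best_j)), next_id)
    labels[labels %in% c(best_i, best_j)] <- next_id
    partitions[[n - step]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  # identical partitions up to label renaming
  all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
}

# brute-force per-record variant predicate (the filter chain as one formula)
variant_oracle_status <- function(rec, normal_keys, min_qc = 20,
                                  max_af = 0.001) {
  vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    flagged <- r$qc < min_qc ||
      (!is.na(r$af_gnomad) && r$af_gnomad > max_af) ||
      (!is.na(r$af_abraom) && r$af_abraom > max_af) ||
      paste(r$chrom, r$pos, r$ref, r$alt, sep = ":") %in% normal_keys
    if (!flagged) "pass"
    else if (r$cosmic_role %in% c("oncogene", "TSG")) "rescued"
    else "removed"
  }, character(1))
}

# brute-force per-record fusion predicate
fusion_oracle_status <- function(rec, blacklist_keys, min_ffpm = 0.1,
                                 min_support = 10, support_mode = "each") {
  vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    support_ok <- if (support_mode == "each")
      r$junction_reads > min_support && r$spanning_frags > min_support
    else r$junction_reads + r$spanning_frags > min_support
    ok <- r$ffpm > min_ffpm && support_ok &&
      !(paste0(r$gene5, "--", r$gene3) %in% blacklist_keys)
    if (ok) "pass" else "removed"
  }, character(1))
}

make_variants <- function(qc = 40, af_gnomad = NA_real_,
                          af_abraom = NA_real_, cosmic_role = "none",
                          chrom = "1", pos = NULL, ref = "A", alt = "T",
                          gene = "GENEX", variant_class = "missense",
                          sample_id = "S01") {
  n <- max(lengths(list(qc, af_gnomad, af_abraom, cosmic_role, chrom,
                        ref, alt, gene, variant_class, sample_id)))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  data.frame(sample_id = rep_len(sample_id, n),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             gene = rep_len(gene, n),
             variant_class = rep_len(variant_class, n),
             qc = rep_len(qc, n),
             af_gnomad = rep_len(af_gnomad, n),
             af_abraom = rep_len(af_abraom, n),
             cosmic_role = rep_len(cosmic_role, n),
             status = "pass", removal_reasons = "",
             stringsAsFactors = FALSE)
}

make_fusions <- function(junction_reads = 20L, spanning_frags = 20L,
                         ffpm = 1, gene5 = "AAA", gene3 = "BBB",
                         sample_id = "S01") {
  n <- max(lengths(list(junction_reads, spanning_frags, ffpm, gene5, gene3,
                        sample_id)))
  data.frame(sample_id = rep_len(sample_id, n),
             gene5 = rep_len(gene5, n), gene3 = rep_len(gene3, n),
             junction_reads = rep_len(junction_reads, n),
             spanning_frags = rep_len(spanning_frags, n),
             ffpm = rep_len(ffpm, n),
             status = "pass", removal_reasons = "",
             stringsAsFactors = FALSE)
}

# small cohort config for fast tests (full gene universe is unnecessary for
# most properties)
small_config <- function(...) {
  cohort_config(n_samples = 30L, n_genes = 600L,
                n_signature_genes = c(BRS = 30L, TDS = 8L, ERK = 20L), ...)
}

# random variant tables spanning all strata, for oracle-equivalence checks
random_variant_table <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(sample_id = sample(c("S01", "S02"), n, TRUE),
               chrom = as.character(sample(1:3, n, TRUE)),
               pos = sample(1:20, n, TRUE) * 10L,
               ref = sample(c("A", "C"), n, TRUE),
               alt = sample(c("G", "T"), n, TRUE),
               gene = sample(c("GENEA", "GENEB"), n, TRUE),
               variant_class = sample(c("missense", "silent"), n, TRUE),
               qc = round(runif(n, 0, 60), 1),
               af_gnomad = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.01)),
               af_abraom = ifelse(runif(n) < 0.6, NA, runif(n, 0, 0.01)),
               cosmic_role = sample(c("none", "oncogene", "TSG"), n, TRUE,
                                    prob = c(0.7, 0.15, 0.15)),
               status = "pass", removal_reasons = "",
               stringsAsFactors = FALSE)
  })
}
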