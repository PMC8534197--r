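# Cluster inference: bootstrapped Hopkins clusterability, consensus choice of
# the number of clusters across an internal validity-index panel with gene
# subsampling, WPGMA (McQuitty) hierarchical clustering, PCA projection,
# outlier flagging and BRAF-like / RAS-like assignment of driver-negative
# samples.
#
# All distances are Euclidean on log2(FPM + 1) profiles. Matrices are genes x
# samples throughout (samples in columns), matching the expression matrix.

# Project samples onto their top-q principal components. Used to compute the
# Hopkins statistic in a reduced space, where nearest-neighbour distances are
# informative (in thousands of dimensions they concentrate).
reduce_pca <- function(mat, q = 10) {
  x <- t(mat)
  q <- min(q, nrow(x) - 1L, ncol(x))
  if (ncol(x) <= q) return(scale(x, center = TRUE, scale = FALSE))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  p$x[, seq_len(max(q, 1L)), drop = FALSE]
}

hopkins_on_points <- function(x, probe_fraction) {
  n <- nrow(x)
  m <- max(1L, round(probe_fraction * n))
  probes <- sample.int(n, m)
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  w <- apply(dm[probes, , drop = FALSE], 1, min)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  u_pts <- matrix(stats::runif(m * ncol(x), rep(lo, each = m),
                               rep(hi, each = m)), nrow = m)
  u <- apply(u_pts, 1, function(pt)
    sqrt(min(colSums((t(x) - pt)^2))))
  denom <- sum(u) + sum(w)
  if (denom == 0) return(0.5)  # all points and pseudo-points coincide
  sum(u) / denom
}

#' Hopkins statistic for clusterability
#'
#' Contrasts nearest-neighbour distances of uniform pseudo-points (drawn in
#' the bounding box of the PCA-reduced data) against those of a subsample of
#' real points: `H = sum(u) / (sum(u) + sum(w))`. H near 1 indicates
#' clustered structure, H near 0.5 spatial randomness; clusterability is
#' declared when `1 - H < 0.5`.
#'
#' @param mat genes x samples matrix (log2 FPM scale).
#' @param probe_fraction fraction of samples used as probes (default 0.1).
#' @param n_components PCA components for the reduced space (default 10,
#'   capped at `n_samples - 1`).
#' @param seed optional seed for the probe and pseudo-point draws.
#' @return H in `[0, 1]`.
#' @export
hopkins_statistic <- function(mat, probe_fraction = 0.1, n_components = 10,
                              seed = NULL) {
  if (ncol(mat) < 3) stopf("hopkins_statistic needs at least 3 samples")
  x <- reduce_pca(mat, n_components)
  with_seed(seed, hopkins_on_points(x, probe_fraction))
}

#' Bootstrapped clusterability decision
#'
#' The Hopkins computation is repeated `reps` times with independent seeds
#' (fresh probe subsample and pseudo-points each time) and the mean of
#' `1 - H` is compared against 0.5.
#'
#' @param mat genes x samples matrix.
#' @param reps bootstrap replicates (default 512).
#' @param probe_fraction,n_components as in [hopkins_statistic()].
#' @param seed master seed for the replicate sub-streams.
#' @return a list with `mean_one_minus_h`, `clusterable` and `reps`.
#' @export
bootstrapped_clusterability <- function(mat, reps = 512, probe_fraction = 0.1,
                                        n_components = 10, seed = 1L) {
  if (ncol(mat) < 3) stopf("clusterability needs at least 3 samples")
  x <- reduce_pca(mat, n_components)
  h <- vapply(seq_len(reps), function(r)
    with_seed(substream_seed(seed, paste0("hopkins", r)),
              hopkins_on_points(x, probe_fraction)),
    numeric(1))
  m <- mean(1 - h)
  list(mean_one_minus_h = m, clusterable = m < 0.5, reps = reps)
}

# ---- internal cluster-validity indices -------------------------------------
# Each index maps the per-k partition summaries to its best k in k_range (or
# NA when the index cannot decide). Partition summaries are computed once per
# bootstrap replicate.

total_wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

# per-partition pair summaries: sums and counts of within/between distances
pair_stats <- function(dvec, same) {
  sw <- sum(dvec[same]); nw <- sum(same)
  sb <- sum(dvec[!same]); nb <- sum(!same)
  list(sw = sw, nw = nw, sb = sb, nb = nb)
}

index_best_k <- function(name, st) {
  kr <- st$k_range
  pick_max <- function(v) kr[which.max(v)]
  pick_min <- function(v) kr[which.min(v)]
  n <- st$n; p <- st$p
  wss <- st$wss
  switch(name,
    calinski_harabasz = {
      ch <- vapply(kr, function(k)
        ((st$tss - wss[[as.character(k)]]) / (k - 1)) /
          (wss[[as.character(k)]] / (n - k)), numeric(1))
      pick_max(ch)
    },
    silhouette = {
      sil <- vapply(kr, function(k)
        mean(cluster::silhouette(st$cuts[[as.character(k)]], st$d)[, 3]),
        numeric(1))
      pick_max(sil)
    },
    davies_bouldin = {
      db <- vapply(kr, function(k) davies_bouldin(st$x,
                                                  st$cuts[[as.character(k)]]),
                   numeric(1))
      pick_min(db)
    },
    dunn = {
      dn <- vapply(kr, function(k) dunn_index(st$dm,
                                              st$cuts[[as.character(k)]]),
                   numeric(1))
      pick_max(dn)
    },
    c_index = {
      ci <- vapply(kr, function(k) {
        ps <- st$pairs[[as.character(k)]]
        if (ps$nw == 0) return(NA_real_)
        smin <- sum(st$dsorted[seq_len(ps$nw)])
        smax <- sum(st$dsorted[seq(length(st$dsorted) - ps$nw + 1,
                                   length(st$dsorted))])
        if (smax == smin) return(NA_real_)
        (ps$sw - smin) / (smax - smin)
      }, numeric(1))
      if (all(is.na(ci))) NA_integer_ else kr[which.min(ci)]
    },
    mcclain_rao = {
      mr <- vapply(kr, function(k) {
        ps <- st$pairs[[as.character(k)]]
        if (ps$nw == 0 || ps$nb == 0 || ps$sb == 0) return(NA_real_)
        (ps$sw / ps$nw) / (ps$sb / ps$nb)
      }, numeric(1))
      if (all(is.na(mr))) NA_integer_ else kr[which.min(mr)]
    },
    point_biserial = {
      sd_d <- stats::sd(st$dvec)
      if (is.na(sd_d) || sd_d == 0) return(NA_integer_)
      nt <- length(st$dvec)
      pb <- vapply(kr, function(k) {
        ps <- st$pairs[[as.character(k)]]
        if (ps$nw == 0 || ps$nb == 0) return(NA_real_)
        mb <- ps$sb / ps$nb; mw <- ps$sw / ps$nw
        (mb - mw) * sqrt(ps$nw * ps$nb / nt^2) / sd_d
      }, numeric(1))
      if (all(is.na(pb))) NA_integer_ else kr[which.max(pb)]
    },
    krzanowski_lai = {
      diffk <- function(k) {
        (k - 1)^(2 / p) * wss[[as.character(k - 1)]] -
          k^(2 / p) * wss[[as.character(k)]]
      }
      kl <- vapply(kr, function(k) {
        d1 <- diffk(k); d2 <- diffk(k + 1)
        if (d2 == 0) return(NA_real_)
        abs(d1 / d2)
      }, numeric(1))
      if (all(is.na(kl))) NA_integer_ else kr[which.max(kl)]
    },
    hartigan = {
      h <- vapply(kr, function(k) {
        w1 <- wss[[as.character(k)]]; w2 <- wss[[as.character(k + 1)]]
        if (w2 == 0) return(NA_real_)
        (w1 / w2 - 1) * (n - k - 1)
      }, numeric(1))
      ok <- which(!is.na(h) & h <= 10)
      if (length(ok)) kr[ok[1]] else NA_integer_
    },
    gap = gap_best_k(st),
    stopf("unknown validity index '%s'", name)
  )
}

davies_bouldin <- function(x, labels) {
  cl <- sort(unique(labels))
  cent <- t(vapply(cl, function(c)
    colMeans(x[labels == c, , drop = FALSE]), numeric(ncol(x))))
  s <- vapply(seq_along(cl), function(i) {
    xi <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_along(cl), function(i) {
    r <- vapply(seq_along(cl), function(j) {
      if (i == j) return(-Inf)
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (m == 0) return(Inf)
      (s[i] + s[j]) / m
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db)
}

dunn_index <- function(dm, labels) {
  cl <- sort(unique(labels))
  min_between <- Inf; max_within <- 0
  for (i in seq_along(cl)) {
    ii <- labels == cl[i]
    di <- dm[ii, ii, drop = FALSE]
    if (sum(ii) > 1) max_within <- max(max_within, max(di))
    for (j in seq_along(cl)) {
      if (j <= i) next
      jj <- labels == cl[j]
      min_between <- min(min_between, min(dm[ii, jj, drop = FALSE]))
    }
  }
  if (max_within == 0) return(Inf)
  min_between / max_within
}

# Gap statistic with uniform reference sets in the bounding box of the data,
# WPGMA partitions, and the one-standard-error rule; falls back to the global
# maximum when no k satisfies the rule.
gap_best_k <- function(st, n_ref = 8) {
  kr <- st$k_range
  ks <- c(kr, max(kr) + 1)
  logw <- vapply(ks, function(k) log(st$wss[[as.character(k)]]), numeric(1))
  lo <- apply(st$x, 2, min); hi <- apply(st$x, 2, max)
  ref_logw <- matrix(NA_real_, n_ref, length(ks))
  for (b in seq_len(n_ref)) {
    xr <- matrix(stats::runif(length(st$x), rep(lo, each = nrow(st$x)),
                              rep(hi, each = nrow(st$x))), nrow = nrow(st$x))
    hc <- stats::hclust(stats::dist(xr), method = "mcquitty")
    ref_logw[b, ] <- vapply(seq_along(ks), function(i) {
      w <- total_wss(xr, stats::cutree(hc, ks[i]))
      log(max(w, .Machine$double.xmin))
    }, numeric(1))
  }
  gap <- colMeans(ref_logw) - logw
  s <- apply(ref_logw, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  for (i in seq_along(kr)) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) return(kr[i])
  }
  kr[which.max(gap[seq_along(kr)])]
}

#' Default internal validity-index panel
#'
#' Ten implementable indices pooled by majority vote: Calinski-Harabasz,
#' average silhouette, Davies-Bouldin, Dunn, C-index, McClain-Rao,
#' point-biserial, Krzanowski-Lai, Hartigan, and the gap statistic.
#' @return character vector of index names.
#' @export
default_index_panel <- function() {
  c("calinski_harabasz", "silhouette", "davies_bouldin", "dunn", "c_index",
    "mcclain_rao", "point_biserial", "krzanowski_lai", "hartigan", "gap")
}

#' Consensus choice of the number of clusters
#'
#' Each bootstrap replicate draws `gene_fraction` of the genes without
#' replacement, builds WPGMA partitions for every k in `k_range`, and lets
#' every validity index vote for one k. The chosen k is the modal vote over
#' all replicates and indices, ties broken toward smaller k (parsimony).
#'
#' @param mat genes x samples matrix.
#' @param k_range candidate cluster numbers (default 2:8).
#' @param indices index panel (default [default_index_panel()]).
#' @param reps bootstrap replicates (default 1080).
#' @param gene_fraction fraction of genes drawn per replicate (default 0.1).
#' @param seed master seed.
#' @return a list with `per_k_votes` (named vector over `k_range`),
#'   `chosen_k`, and `n_invalid` (index evaluations that returned no k).
#' @export
consensus_cluster_number <- function(mat, k_range = 2:8,
                                     indices = default_index_panel(),
                                     reps = 1080, gene_fraction = 0.1,
                                     seed = 1L) {
  n <- ncol(mat)
  k_range <- as.integer(k_range)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stopf("k_range must lie within [2, n_samples - 1]")
  if (n < max(k_range) + 1)
    stopf("need at least max(k_range) + 1 samples")
  if (!length(indices)) stopf("index panel must be non-empty")
  votes <- stats::setNames(rep(0L, length(k_range)), k_range)
  n_invalid <- 0L
  n_draw <- max(2L, round(gene_fraction * nrow(mat)))
  ks_all <- seq(min(k_range) - 1L, min(max(k_range) + 1L, n))
  for (r in seq_len(reps)) {
    res <- with_seed(substream_seed(seed, paste0("consensus", r)), {
      gsub_idx <- sample.int(nrow(mat), n_draw)
      x <- t(mat[gsub_idx, , drop = FALSE])
      d <- stats::dist(x)
      hc <- stats::hclust(d, method = "mcquitty")
      cuts <- lapply(ks_all, function(k) stats::cutree(hc, k))
      names(cuts) <- ks_all
      dvec <- as.vector(d)
      dm <- as.matrix(d)
      same_of <- function(labels) {
        pr <- outer(labels, labels, "==")
        pr[lower.tri(pr)]
      }
      # note: as.vector(dist) is column-major lower triangle, matching
      # lower.tri() ordering
      st <- list(
        k_range = k_range, n = n, p = ncol(x), x = x, d = d, dm = dm,
        dvec = dvec, dsorted = sort(dvec),
        cuts = cuts,
        wss = stats::setNames(lapply(cuts, function(l) total_wss(x, l)),
                              ks_all),
        tss = total_wss(x, rep(1L, n)),
        pairs = stats::setNames(lapply(as.character(k_range), function(k)
          pair_stats(dvec, same_of(cuts[[k]]))), k_range))
      vapply(indices, function(nm) {
        k <- tryCatch(index_best_k(nm, st), error = function(e) NA_integer_)
        if (is.null(k) || is.na(k)) NA_integer_ else as.integer(k)
      }, integer(1))
    })
    valid <- res[!is.na(res)]
    n_invalid <- n_invalid + sum(is.na(res))
    for (k in valid) votes[as.character(k)] <- votes[as.character(k)] + 1L
  }
  chosen <- k_range[which.max(votes)]  # which.max returns first = smallest k
  list(per_k_votes = votes, chosen_k = chosen, n_invalid = n_invalid,
       n_evaluations = as.integer(reps * length(indices)))
}

#' WPGMA (McQuitty) hierarchical clustering
#'
#' Agglomerative clustering with the WPGMA update
#' `d(new, x) = (d(a, x) + d(b, x)) / 2` after merging a and b; labels come
#' from cutting the tree into k groups.
#'
#' @param mat genes x samples matrix.
#' @param k number of clusters.
#' @param distance distance method passed to [stats::dist()] (default
#'   Euclidean).
#' @return a list with `tree` (an `hclust` object), `labels` (named cluster
#'   ids) and `heights`.
#' @export
wpgma_cluster <- function(mat, k, distance = "euclidean") {
  n <- ncol(mat)
  if (k > n) stopf("k = %d exceeds the number of samples (%d)", k, n)
  hc <- stats::hclust(stats::dist(t(mat), method = distance),
                      method = "mcquitty")
  labels <- stats::cutree(hc, k)
  list(tree = hc, labels = labels, heights = hc$height)
}

#' PCA projection of samples
#'
#' Gene-centred sample profiles projected on the top right singular vectors.
#' Component signs are fixed so that each component's largest-magnitude gene
#' loading is positive, making coordinates reproducible across platforms.
#'
#' @param mat genes x samples matrix.
#' @param n_components number of components (default 2).
#' @return samples x components coordinate matrix.
#' @export
pca_project <- function(mat, n_components = 2) {
  x <- t(mat)
  if (nrow(x) < 2) stopf("pca_project needs at least 2 samples")
  if (n_components > min(dim(x)))
    stopf("n_components exceeds matrix rank bound")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$x))
  coords <- p$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    load <- p$rotation[, j]
    i <- which.max(abs(load))
    if (load[i] < 0) coords[, j] <- -coords[, j]
  }
  if (nc < n_components)  # rank-deficient (e.g. identical samples)
    coords <- cbind(coords, matrix(0, nrow(coords), n_components - nc))
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  coords
}

#' Flag expression outliers by mean inter-sample distance
#'
#' A sample is an outlier when its mean Euclidean distance to all other
#' samples exceeds the cohort mean of that quantity by more than
#' `z_threshold` standard deviations. Outliers are excluded from clustering
#' but still reported and scored.
#'
#' @param mat genes x samples matrix.
#' @param z_threshold flagging threshold in SD units (default 3).
#' @return character vector of outlier sample names (possibly empty).
#' @export
flag_outliers <- function(mat, z_threshold = 3) {
  n <- ncol(mat)
  if (n < 4) stopf("flag_outliers needs at least 4 samples")
  dm <- as.matrix(stats::dist(t(mat)))
  md <- rowSums(dm) / (n - 1)
  s <- stats::sd(md)
  if (is.na(s) || s == 0) return(character(0))
  names(md)[md > mean(md) + z_threshold * s]
}

#' Assign driver-negative samples to BRAF-like / RAS-like groups
#'
#' Each cluster is typed by the majority driver mutation among its
#' driver-positive members (BRAF V600E versus RAS / PAX8-PPARg); negatives
#' inherit their cluster's type as `negative-BL` or `negative-RL`. Negatives
#' carrying a flagged histology (e.g. Hurthle-cell) are reported separately
#' as `negative-other`. A cluster containing unflagged negatives but no
#' driver-positive members, or with a tied majority, raises an error naming
#' the affected negatives -- no silent choice is made.
#'
#' @param labels named cluster ids (from [wpgma_cluster()]).
#' @param driver_status named vector over the same samples with values
#'   `positive-BRAF`, `positive-RAS`, `positive-PAX8-PPARg`, `negative`.
#' @param histology optional named vector; samples whose value is in
#'   `other_histologies` are assigned `negative-other`.
#' @param other_histologies histology labels reported separately
#'   (default `"HCC"`).
#' @return named character vector over the driver-negative samples with
#'   values `negative-BL`, `negative-RL`, `negative-other`.
#' @export
assign_negative_classes <- function(labels, driver_status, histology = NULL,
                                    other_histologies = "HCC") {
  miss <- setdiff(names(labels), names(driver_status))
  if (length(miss))
    stopf("driver status missing for samples: %s", paste(miss, collapse = ", "))
  out <- character(0)
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    status <- driver_status[ids]
    negs <- ids[status == "negative"]
    if (!is.null(histology)) {
      other <- negs[histology[negs] %in% other_histologies]
      out[other] <- "negative-other"
      negs <- setdiff(negs, other)
    }
    if (!length(negs)) next
    n_braf <- sum(status == "positive-BRAF")
    n_ras <- sum(status %in% c("positive-RAS", "positive-PAX8-PPARg"))
    if (n_braf == 0 && n_ras == 0)
      stopf("unresolved cluster %s: no driver-positive members; affected negatives: %s",
            cl, paste(negs, collapse = ", "))
    if (n_braf == n_ras)
      stopf("unresolved cluster %s: tied driver majority (%d BRAF vs %d RAS); affected negatives: %s",
            cl, n_braf, n_ras, paste(negs, collapse = ", "))
    out[negs] <- if (n_braf > n_ras) "negative-BL" else "negative-RL"
  }
  out
}
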