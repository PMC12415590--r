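#' Neuroanatomical subtyping on shared differential edges
#'
#' Cohort-level feature construction and clustering. Edges are ranked by
#' how many patients carry them as FDR-significant (ties broken by mean
#' |Z| across patients, then by canonical edge order), the top-K edges'
#' signed Z values form the patients x K feature matrix, and patients are
#' clustered by k-means with the cluster number chosen by mean silhouette
#' over a grid.
#'
#' @name subtyping
NULL

#' Rank edges by cross-patient significance frequency
#'
#' Deterministic total order: descending count of patients in which the
#' edge is FDR-significant, ties broken by descending mean |Z| across
#' patients, remaining ties by canonical edge order.
#'
#' @param idscns List of `patient_idscn` with edge selection applied.
#' @return Object of class `edge_ranking`: data.frame `i`, `j`, `freq`,
#'   `mean_abs_z` in rank order, with the number of patients as attribute
#'   `n_patients`.
#' @export
rank_edges <- function(idscns) {
  if (length(idscns) < 2) stop("need at least 2 patients to rank edges")
  freq <- Reduce(`+`, lapply(idscns, function(x) {
    if (is.null(x$sig_mask)) stop("run select_significant_edges() first")
    flatten_edges(x$sig_mask) + 0L
  }))
  mean_abs_z <- Reduce(`+`, lapply(idscns, function(x) abs(flatten_edges(x$z)))) /
    length(idscns)
  e <- edge_universe(nrow(idscns[[1]]$z))
  ord <- order(-freq, -mean_abs_z, seq_along(freq))
  out <- data.frame(i = e$i[ord], j = e$j[ord],
                    freq = freq[ord], mean_abs_z = mean_abs_z[ord])
  rownames(out) <- NULL
  attr(out, "n_patients") <- length(idscns)
  class(out) <- c("edge_ranking", "data.frame")
  out
}

#' Build the patients x K feature matrix of top-ranked edges
#'
#' @param idscns List of `patient_idscn`.
#' @param ranking An `edge_ranking` from [rank_edges()].
#' @param K Number of top edges to keep as features.
#' @param value Feature value: signed `"z"` (default), `"abs_z"`, or
#'   binary `"sig"`.
#' @return Numeric matrix, patient IDs as rownames, `i-j` edge keys as
#'   colnames, with the selected edges as attribute `edges`.
#' @export
build_feature_matrix <- function(idscns, ranking, K, value = c("z", "abs_z", "sig")) {
  value <- match.arg(value)
  if (K <= 0) stop("K must be positive")
  if (K > nrow(ranking)) stop("K exceeds the edge universe size")
  top <- ranking[seq_len(K), c("i", "j")]
  idx <- cbind(top$i, top$j)
  vals <- vapply(idscns, function(x) {
    switch(value,
           z = x$z[idx],
           abs_z = abs(x$z[idx]),
           sig = as.numeric(x$sig_mask[idx]))
  }, numeric(K))
  feat <- if (K == 1) matrix(vals, ncol = 1) else t(vals)
  rownames(feat) <- unname(vapply(idscns, function(x) x$patient_id, character(1)))
  colnames(feat) <- paste(top$i, top$j, sep = "-")
  attr(feat, "edges") <- top
  feat
}

#' Canonical relabeling: cluster 1 = largest cluster
#'
#' Clusters are renumbered by decreasing size; size ties are broken by the
#' lowest member index. Keeps labels, and hence reports and agreement
#' indices, stable across runs.
#' @param labels Integer cluster labels.
#' @return Relabeled integer vector (same names).
#' @export
canonical_labels <- function(labels) {
  sizes <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.integer(sizes), first)
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- as.integer(map[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' Cluster patients by k-means with silhouette-based model selection
#'
#' For each candidate k the k-means is restarted `n_repeats` times from
#' seeded random initializations and the lowest-inertia solution kept; the
#' mean silhouette width (Euclidean distance, computed on the same feature
#' space) selects the cluster number. No feature standardization is
#' applied: Z-scores already share a scale.
#'
#' @param features Patients x K feature matrix.
#' @param k_grid Candidate cluster numbers (default 2:20; truncated with a
#'   warning if it exceeds `n_patients - 1`).
#' @param n_repeats Random initializations per k (default 100).
#' @param seed Seed controlling all initializations.
#' @return Object of class `subtype_solution`: list with `chosen_k`,
#'   `labels` (canonical, named by patient), `silhouette_by_k`
#'   (data.frame `k`, `mean_silhouette`, `inertia`), `k_grid`,
#'   `n_repeats`, `seed`, `features_K`.
#' @export
cluster_patients <- function(features, k_grid = 2:20, n_repeats = 100, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  n_distinct <- nrow(unique(features))
  if (n_distinct < 2) stop("degenerate features: fewer than 2 distinct patient rows")
  if (max(k_grid) > n - 1) {
    warning("k_grid truncated to n_patients - 1 = ", n - 1)
    k_grid <- k_grid[k_grid <= n - 1]
  }
  k_grid <- k_grid[k_grid >= 2 & k_grid <= n_distinct]
  if (!length(k_grid)) stop("empty k grid after truncation")
  d <- stats::dist(features)
  sil <- numeric(length(k_grid))
  inertia <- numeric(length(k_grid))
  fits <- vector("list", length(k_grid))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    fit <- stats::kmeans(features, centers = k, nstart = n_repeats,
                         iter.max = 100)
    fits[[ki]] <- fit
    inertia[ki] <- fit$tot.withinss
    sw <- cluster::silhouette(fit$cluster, d)
    sil[ki] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)
  labels <- canonical_labels(fits[[best]]$cluster)
  names(labels) <- rownames(features)
  structure(list(
    chosen_k = k_grid[best], labels = labels,
    silhouette_by_k = data.frame(k = k_grid, mean_silhouette = sil,
                                 inertia = inertia),
    k_grid = k_grid, n_repeats = n_repeats, seed = seed,
    features_K = ncol(features)
  ), class = "subtype_solution")
}

#' @export
print.subtype_solution <- function(x, ...) {
  cat("<subtype_solution> chosen k = ", x$chosen_k, " (silhouette ",
      sprintf("%.3f", max(x$silhouette_by_k$mean_silhouette)),
      "), cluster sizes: ",
      paste(table(x$labels), collapse = "/"), "\n", sep = "")
  invisible(x)
}

# save/restore RNG state so seeded subroutines do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-adjusted Rand index from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - E}}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}.
#' Invariant to label renaming; 1 for identical partitions, about 0 for
#' independent ones. Returns 1 when both partitions are single clusters
#' (the index is 0/0 there; identical trivial partitions agree perfectly).
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 subjects")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  expected <- a * b / ch2(n)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Reproducibility of subtyping across feature-set sizes
#'
#' Re-runs ranking-based feature construction and clustering for each K in
#' `K_list` and reports the adjusted Rand index for every unordered pair
#' of solutions.
#'
#' @param idscns List of `patient_idscn` with edge selection applied.
#' @param K_list Top-edge counts to compare (default 60, 70, 80, 90).
#' @param k_grid,n_repeats,seed Passed to [cluster_patients()].
#' @param value Passed to [build_feature_matrix()].
#' @return List with `solutions` (named by K), `ari` (symmetric matrix,
#'   unit diagonal) and `pairs` (data.frame `K_a`, `K_b`, `ari`).
#' @export
stability_analysis <- function(idscns, K_list = c(60, 70, 80, 90),
                               k_grid = 2:20, n_repeats = 100, seed = 1,
                               value = "z") {
  ranking <- rank_edges(idscns)
  if (max(K_list) > nrow(ranking)) stop("K exceeds the edge universe size")
  sols <- lapply(K_list, function(K) {
    feat <- build_feature_matrix(idscns, ranking, K, value = value)
    cluster_patients(feat, k_grid = k_grid, n_repeats = n_repeats, seed = seed)
  })
  names(sols) <- as.character(K_list)
  m <- length(K_list)
  ari <- matrix(1, m, m, dimnames = list(K_list, K_list))
  pairs <- NULL
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a < b) {
      v <- adjusted_rand_index(sols[[a]]$labels, sols[[b]]$labels)
      ari[a, b] <- ari[b, a] <- v
      pairs <- rbind(pairs, data.frame(K_a = K_list[a], K_b = K_list[b], ari = v))
    }
  }
  list(solutions = sols, ari = ari, pairs = pairs)
}
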