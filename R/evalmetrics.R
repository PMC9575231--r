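#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells: 1 for
#' identical partitions (up to relabeling), expectation 0 under random
#' labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) < 2L) stop("need at least 2 observations")
  mclust::adjustedRandIndex(a, b)
}

#' Mean silhouette width of a labeled embedding
#'
#' Average over cells of `(b - a) / max(a, b)` with Euclidean distances, where
#' `a` is the mean within-cluster distance and `b` the smallest mean
#' between-cluster distance.
#'
#' @param e Numeric matrix (cells x dims).
#' @param labels Cluster labels per row.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(e, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  if (all(table(labels) < 2L)) stop("all clusters are singletons")
  sil <- cluster::silhouette(labels, stats::dist(e))
  mean(sil[, "sil_width"])
}

#' K-means clustering with many restarts
#'
#' Hartigan-Wong K-means with `restarts` random starts and up to `max_iter`
#' iterations (the convention used throughout the benchmarking: nstart 300,
#' iter.max 1000), deterministic given `seed`.
#'
#' @param e Numeric matrix (cells x dims).
#' @param k Number of clusters.
#' @param restarts Random restarts.
#' @param max_iter Maximum iterations.
#' @param seed RNG seed.
#' @return Integer label vector.
#' @export
kmeans_labels <- function(e, k, restarts = 300, max_iter = 1000, seed = 1) {
  e <- as.matrix(e)
  if (k > nrow(e)) stop("k exceeds the number of cells")
  if (k == nrow(e)) return(seq_len(k))  # every point its own cluster
  set.seed(seed)
  stats::kmeans(e, centers = k, nstart = restarts, iter.max = max_iter)$cluster
}

#' Louvain clustering tuned to a target cluster number
#'
#' Builds a shared-nearest-neighbor (SNN) graph with Jaccard edge weights,
#' runs Louvain modularity community detection, and bisects the resolution
#' parameter on `[1e-3, 10]` until the community count matches `k_target` or
#' the iteration budget is exhausted; the closest-count labeling is returned
#' (with a warning when the target is unreachable).
#'
#' @param e Numeric matrix (cells x dims).
#' @param k_target Desired number of communities.
#' @param k_neighbors Neighbors for the SNN graph.
#' @param tol_iter Bisection steps.
#' @param seed RNG seed (Louvain is stochastic).
#' @return Integer label vector.
#' @export
louvain_target_k <- function(e, k_target, k_neighbors = 20, tol_iter = 30,
                             seed = 1) {
  e <- as.matrix(e)
  if (nrow(e) <= k_neighbors) stop("need more cells than k_neighbors")
  sim <- snn_similarity(e, k = k_neighbors)
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  run <- function(res) {
    set.seed(seed)
    igraph::cluster_louvain(g, resolution = res)$membership
  }
  lo <- 1e-3; hi <- 10
  best <- NULL; best_gap <- Inf
  for (i in seq_len(tol_iter)) {
    mid <- (lo + hi) / 2
    mem <- run(mid)
    k <- length(unique(mem))
    gap <- abs(k - k_target)
    if (gap < best_gap) {
      best <- mem; best_gap <- gap
    }
    if (k == k_target) break
    if (k < k_target) lo <- mid else hi <- mid
  }
  if (best_gap > 0) {
    warning("target cluster number ", k_target, " not reached; returning ",
            length(unique(best)), " communities")
  }
  best
}

#' Integration local inverse Simpson's index (iLISI)
#'
#' Per-cell effective number of batches in the cell's neighborhood: Gaussian
#' kernel weights calibrated to the given perplexity are summed per batch and
#' the inverse Simpson index `1 / sum_b p_b^2` is returned. Scores lie in
#' `[1, B]`; a density near 1 indicates that neighborhoods contain a single
#' batch (strong batch effect), larger values indicate good mixing.
#'
#' @param e Numeric matrix (cells x dims).
#' @param batches Batch label per row.
#' @param perplexity Kernel perplexity (effective neighborhood size).
#' @return Numeric vector of per-cell scores.
#' @export
ilisi_scores <- function(e, batches, perplexity = 30) {
  e <- as.matrix(e)
  n <- nrow(e)
  if (n < 2L) stop("need at least 2 cells")
  if (perplexity >= n) stop("perplexity must be below the number of cells")
  batches <- as.character(batches)
  levels_b <- unique(batches)
  if (length(levels_b) == 1L) return(rep(1, n))
  k_use <- min(n - 1L, max(as.integer(ceiling(3 * perplexity)), 3L))
  dmat <- as.matrix(stats::dist(e))
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ])
    nb <- setdiff(ord, i)[seq_len(k_use)]
    d2 <- dmat[i, nb]^2
    # binary search the precision so the kernel entropy matches log(perplexity)
    beta <- 1
    lo <- 0; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw == 0) { hi <- beta; beta <- beta / 2; next }
      h <- log(sw) + beta * sum(d2 * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    w <- exp(-d2 * beta)
    if (sum(w) == 0) w <- rep(1, length(nb))
    p <- w / sum(w)
    pb <- vapply(levels_b, function(b) sum(p[batches[nb] == b]), numeric(1))
    out[i] <- 1 / sum(pb^2)
  }
  out
}

#' Shared-nearest-neighbor Jaccard similarity
#'
#' For each cell, its `k`-nearest-neighbor set (Euclidean, self included);
#' similarity between two cells is the Jaccard overlap of their neighbor
#' sets. Symmetric, values in `[0, 1]`, diagonal set to 0 by convention.
#'
#' @param e Numeric matrix (cells x dims).
#' @param k Neighborhood size.
#' @return Dense symmetric similarity matrix with zero diagonal.
#' @export
snn_similarity <- function(e, k = 20) {
  e <- as.matrix(e)
  n <- nrow(e)
  if (n <= k) stop("need more cells than k")
  dmat <- as.matrix(stats::dist(e))
  # neighbor sets include the cell itself plus its k - 1 nearest others,
  # with ties broken by index for determinism
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ], seq_len(n))
    ord <- c(i, setdiff(ord, i))
    nb[i, ] <- ord[seq_len(k)]
  }
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.vector(t(nb)),
    x = 1,
    dims = c(n, n)
  )
  inter <- as.matrix(ind %*% Matrix::t(ind))
  sim <- inter / (2 * k - inter)
  diag(sim) <- 0
  if (!is.null(rownames(e))) dimnames(sim) <- list(rownames(e), rownames(e))
  sim
}

#' Hierarchical cell-type dendrogram from a similarity matrix
#'
#' Average-linkage hierarchical clustering on `distance = 1 - similarity`,
#' plus per-type purity: at the cut into as many clusters as there are types,
#' the fraction of each type's cells falling in its majority cluster.
#'
#' @param sim Square symmetric similarity matrix.
#' @param labels Cell type per row.
#' @return List with `hclust` (the tree) and `purity` (tibble `type`,
#'   `n_cells`, `purity`).
#' @export
celltype_dendrogram <- function(sim, labels) {
  sim <- as.matrix(sim)
  if (!isSymmetric(unname(sim), tol = 1e-8)) {
    stop("similarity matrix must be symmetric")
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  k <- length(unique(labels))
  cut <- stats::cutree(hc, k = k)
  purity <- tibble::tibble(type = as.character(labels), cluster = cut) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      purity = max(table(.data$cluster)) / dplyr::n(),
      .groups = "drop"
    )
  list(hclust = hc, purity = purity)
}

#' Project an embedding onto its top principal components
#'
#' The benchmarking convention: vectorized cell-by-pair matrices (or model
#' embeddings) are reduced to the top 50 principal components before t-SNE /
#' UMAP or clustering.
#'
#' @param m Numeric or sparse matrix (cells x features).
#' @param n_pcs Number of components (default 50; capped at the matrix rank).
#' @return Dense matrix (cells x `n_pcs`).
#' @export
embed_pca <- function(m, n_pcs = 50) {
  m <- as.matrix(m)
  n_pcs <- min(n_pcs, nrow(m) - 1L, ncol(m))
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  p$x
}

#' Run the clustering evaluation harness
#'
#' The six-setting benchmark: K-means and Louvain clustering applied to the
#' supplied embedding and to any number of externally computed 2-D projections
#' (e.g. t-SNE, UMAP), each scored with ARI against the true labels and with
#' the mean silhouette of the true labels in that space.
#'
#' @param e Numeric matrix (cells x dims), typically PCA-reduced.
#' @param labels True cell types.
#' @param projections Named list of additional (cells x 2) projections.
#' @param k Number of clusters; default the number of distinct labels.
#' @param seed RNG seed.
#' @return Tibble `space`, `method`, `ari`, `silhouette`.
#' @export
clustering_benchmark <- function(e, labels, projections = list(), k = NULL,
                                 seed = 1) {
  if (is.null(k)) k <- length(unique(labels))
  spaces <- c(list(embedding = as.matrix(e)), projections)
  res <- list()
  for (nm in names(spaces)) {
    sp <- as.matrix(spaces[[nm]])
    km <- kmeans_labels(sp, k, seed = seed)
    lv <- tryCatch(louvain_target_k(sp, k, seed = seed),
                   error = function(e) NULL)
    sil <- mean_silhouette(sp, labels)
    res[[length(res) + 1L]] <- tibble::tibble(
      space = nm, method = "kmeans",
      ari = adjusted_rand_index(km, labels), silhouette = sil
    )
    if (!is.null(lv)) {
      res[[length(res) + 1L]] <- tibble::tibble(
        space = nm, method = "louvain",
        ari = adjusted_rand_index(lv, labels), silhouette = sil
      )
    }
  }
  dplyr::bind_rows(res)
}
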