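# Multivariate source-identification statistics: z-score standardization,
# Pearson correlation, PCA, Ward hierarchical clustering, and k-means with
# elbow/silhouette model selection.

#' Z-score standardization by column
#'
#' Centers each column to mean 0 and scales to sample (n-1) standard
#' deviation 1. Constant columns have no scale and are rejected.
#'
#' @param x numeric matrix (sites x elements).
#' @return standardized matrix with the same dimnames.
#' @export
zscore_standardize <- function(x) {
  x <- as.matrix(unclass(x))
  if (!is.numeric(x)) stopf("standardization requires a numeric matrix")
  sds <- apply(x, 2L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0L) {
    nm <- colnames(x)[zero[1L]]
    stopf("constant column cannot be standardized: %s",
          if (is.null(nm)) as.character(zero[1L]) else nm)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Pearson correlation matrix
#'
#' Product-moment correlations between columns. Zero-variance columns give
#' undefined entries, reported as `NA` with a warning.
#'
#' @param x numeric matrix with at least 3 rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(unclass(x))
  if (nrow(x) < 3L) stopf("correlation requires at least 3 rows")
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  if (any(sds == 0)) {
    warnf("zero-variance column(s): correlation undefined (NA) for %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  diag(r)[is.finite(diag(r))] <- 1
  r
}

#' Principal component analysis of a standardized matrix
#'
#' Singular value decomposition of the (already standardized) input.
#' Components are ordered by decreasing explained variance; the sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making results deterministic. Explained variance fractions
#' are reported over all components and sum to 1.
#'
#' @param x standardized numeric matrix (use [zscore_standardize()]).
#' @param n_components number of components to return; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return object of class `"pca_result"`: list with `loadings`
#'   (variables x components), `scores` (rows x components),
#'   `explained_variance` (fractions for the returned components) and
#'   `all_variance` (fractions for every component, summing to 1).
#' @export
pca_decomposition <- function(x, n_components = NULL) {
  x <- as.matrix(unclass(x))
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1L || n_components > max_comp) {
    stopf("n_components must be between 1 and min(n_rows - 1, n_cols) = %d", max_comp)
  }
  s <- svd(x)
  ev <- s$d^2
  fractions <- ev / sum(ev)
  loadings <- s$v
  scores <- s$u %*% diag(s$d, nrow = length(s$d))
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncol(scores))))
  structure(
    list(
      loadings = loadings[, seq_len(n_components), drop = FALSE],
      scores = scores[, seq_len(n_components), drop = FALSE],
      explained_variance = fractions[seq_len(n_components)],
      all_variance = fractions
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA decomposition\n")
  cat("  components:", ncol(x$loadings), "\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  cat("  cumulative:",
      sprintf("%.1f%%", 100 * sum(x$explained_variance)), "\n")
  invisible(x)
}

#' Ward hierarchical clustering of sites or elements
#'
#' Agglomerative clustering with Euclidean distances and Ward's
#' minimum-variance linkage (`stats::hclust`, method `"ward.D2"`). In
#' `"elements"` mode the input is transposed so columns are clustered.
#' Merge heights are the Ward distances `sqrt(2 * deltaSS)` and are
#' monotone non-decreasing.
#'
#' @param x standardized numeric matrix (sites x elements).
#' @param mode cluster rows (`"sites"`) or columns (`"elements"`).
#' @param k optional number of clusters at which to cut the tree.
#' @return object of class `"hca_result"`: list with `mode`, `tree` (the
#'   `hclust` object), `merges`, `heights`, `labels` (cluster memberships
#'   if `k` given, else `NULL`) and `k`.
#' @export
hierarchical_cluster <- function(x, mode = c("sites", "elements"), k = NULL) {
  mode <- match.arg(mode)
  m <- as.matrix(unclass(x))
  if (mode == "elements") m <- t(m)
  if (nrow(m) < 2L) stopf("clustering requires at least 2 items")
  tree <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  labels <- NULL
  if (!is.null(k)) {
    if (k < 1L || k > nrow(m)) stopf("k must be between 1 and %d", nrow(m))
    labels <- stats::cutree(tree, k = k)
  }
  structure(
    list(mode = mode, tree = tree, merges = tree$merge, heights = tree$height,
         labels = labels, k = k),
    class = "hca_result"
  )
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("Ward hierarchical clustering (%s mode): %d items, %d merges\n",
              x$mode, length(x$tree$order), nrow(x$merges)))
  if (!is.null(x$labels)) {
    cat(sprintf("  cut at k = %d:\n", x$k))
    print(x$labels)
  }
  invisible(x)
}

#' K-means clustering with multi-start Lloyd iterations
#'
#' Runs Lloyd's algorithm from `nstart` random initializations and keeps
#' the solution with the lowest within-cluster sum of squares. Seeded for
#' reproducibility. `k = n` returns the trivial partition with zero
#' inertia.
#'
#' @param x numeric matrix of observations (rows).
#' @param k number of clusters, `2 <= k <= nrow(x)` (k = 1 also accepted).
#' @param seed integer seed controlling the random restarts.
#' @param nstart number of random restarts (default 10).
#' @return list with `labels` (integer vector), `inertia` (total
#'   within-cluster sum of squares) and `centers`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, nstart = 10L) {
  m <- as.matrix(unclass(x))
  n <- nrow(m)
  if (k > n) stopf("k (%d) cannot exceed the number of observations (%d)", k, n)
  if (k < 1L) stopf("k must be at least 1")
  if (k == n) {
    labels <- stats::setNames(seq_len(n), rownames(m))
    return(list(labels = labels, inertia = 0, centers = m))
  }
  # Lloyd restarts occasionally produce an empty cluster (a warning); such
  # runs lose the best-inertia comparison and are harmless under multi-start
  fit <- with_seed(seed, suppressWarnings(
    stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100L,
                  algorithm = "Lloyd")
  ))
  list(labels = stats::setNames(fit$cluster, rownames(m)),
       inertia = fit$tot.withinss, centers = fit$centers)
}

#' Select the number of clusters by silhouette (with elbow diagnostics)
#'
#' For each candidate k, fits seeded multi-start k-means and records the
#' within-cluster sum of squares (the elbow curve) and the mean silhouette
#' width. The selected k maximizes the mean silhouette; the elbow curve is
#' returned for inspection, not auto-interpreted.
#'
#' @param x numeric matrix of observations (rows).
#' @param k_range integer candidates, within `2 .. nrow(x) - 1`.
#' @param seed integer seed for the k-means restarts.
#' @param nstart restarts per k.
#' @return list with `k_selected`, `diagnostics` (data.frame
#'   `k, wcss, mean_silhouette`) and `labels` (memberships at the selected
#'   k).
#' @export
select_k <- function(x, k_range = 2:10, seed = 1L, nstart = 10L) {
  m <- as.matrix(unclass(x))
  n <- nrow(m)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stopf("k_range must lie within 2 .. n - 1 = %d", n - 1L)
  }
  if (all(stats::dist(m) == 0)) {
    stopf("all observations identical: cluster-count selection is degenerate")
  }
  d <- stats::dist(m)
  diagnostics <- do.call(rbind, lapply(k_range, function(k) {
    fit <- kmeans_cluster(m, k, seed = seed + k, nstart = nstart)
    sil <- cluster::silhouette(fit$labels, d)
    data.frame(k = k, wcss = fit$inertia, mean_silhouette = mean(sil[, "sil_width"]))
  }))
  k_selected <- diagnostics$k[which.max(diagnostics$mean_silhouette)]
  best <- kmeans_cluster(m, k_selected, seed = seed + k_selected, nstart = nstart)
  list(k_selected = k_selected, diagnostics = diagnostics, labels = best$labels)
}
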