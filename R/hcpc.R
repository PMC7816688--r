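# Hierarchical clustering on principal components (HCPC):
# (1) PCA of the isolate x position alternative-frequency matrix,
# (2) Ward agglomeration on the retained component scores,
# (3) tree cut, (4) k-means consolidation seeded at the cut centroids.
# The consolidation is deterministic (no random restarts), so the whole
# pipeline is seed-free.

#' PCA of an alternative-frequency matrix
#'
#' Columns are centred and, by default, standardised to unit variance.
#' Zero-variance columns are dropped with a warning when scaling. A
#' deterministic sign convention is applied: in every component the loading
#' of largest magnitude is made positive.
#'
#' @param freq isolates x positions numeric matrix (see [freq_matrix()])
#' @param scale logical; standardise columns to unit variance (default TRUE)
#' @return list of class `pca_result`: `scores` (isolates x components),
#'   `loadings`, `eigenvalues`, `percent` (variance per component),
#'   `cumulative`, `n_components`, `center`, `scale`
#' @export
run_pca <- function(freq, scale = TRUE) {
  if (nrow(freq) < 2 || ncol(freq) < 2)
    stop("need at least 2 isolates and 2 positions")
  if (scale) {
    v <- apply(freq, 2, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance column(s) dropped before scaling")
      freq <- freq[, v > 0, drop = FALSE]
    }
  }
  p <- prcomp(freq, center = TRUE, scale. = scale)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    k <- which.max(abs(p$rotation[, j]))
    if (p$rotation[k, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2
  pct <- 100 * ev / sum(ev)
  structure(list(scores = p$x, loadings = p$rotation, eigenvalues = ev,
                 percent = pct, cumulative = cumsum(pct),
                 n_components = length(ev),
                 center = p$center, scale = p$scale),
            class = "pca_result")
}

#' @method print pca_result
#' @param x object to print
#' @param ... unused
#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components; first 7 cover %.1f%% of variance\n",
              x$n_components,
              x$cumulative[min(7, x$n_components)]))
  invisible(x)
}

within_inertia <- function(scores, cluster) {
  sum(vapply(split(seq_len(nrow(scores)), cluster), function(i) {
    m <- scores[i, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
}

#' Ward clustering of isolates on retained principal components
#'
#' Euclidean distances over the first `n_components` scores, agglomerated
#' with the Ward.D2 criterion. The within-cluster inertia W(k) is computed
#' for every cut, the inertia gains g(k) = W(k-1) - W(k) are reported, and
#' the suggested cluster count is the k (2 <= k < n-1) with the largest
#' relative gain drop, i.e. maximising g(k) / g(k+1).
#'
#' @param pca a `pca_result`
#' @param n_components number of leading components to retain (default 7)
#' @param method agglomeration criterion passed to [stats::hclust()]
#' @return list of class `hc_result`: `hclust`, `scores` (retained),
#'   `inertia` (W(k) for k = 1..n), `gains`, `suggested_k`
#' @export
hierarchical_cluster <- function(pca, n_components = 7, method = "ward.D2") {
  if (n_components > pca$n_components)
    stop("n_components exceeds available components")
  s <- pca$scores[, seq_len(n_components), drop = FALSE]
  hc <- hclust(dist(s), method = method)
  n <- nrow(s)
  W <- vapply(seq_len(n), function(k)
    within_inertia(s, cutree(hc, k = k)), numeric(1))
  gains <- -diff(W)  # gains[k-1] = W(k-1) - W(k)
  suggested <- NA_integer_
  if (n >= 4) {
    ks <- 2:(n - 2)
    ratio <- gains[ks - 1] / pmax(gains[ks], .Machine$double.eps)
    suggested <- ks[which.max(ratio)]
  }
  structure(list(hclust = hc, scores = s, inertia = W, gains = gains,
                 suggested_k = suggested),
            class = "hc_result")
}

#' Cut the tree and consolidate with k-means
#'
#' The tree is cut at `k` clusters; k-means is then initialised at the cut
#' clusters' centroids and run to convergence, which can only decrease the
#' total within-cluster inertia. Both assignments are returned together with
#' factor-map coordinates (scores on the first two components).
#'
#' @param hc an `hc_result`
#' @param k number of clusters (default 6)
#' @return list of class `hcpc_result`: `k`, `tree_assignment`,
#'   `assignment` (after consolidation), `centers`, `within_before`,
#'   `within_after`, `factor_map`, `hclust`
#' @export
cut_and_consolidate <- function(hc, k = 6) {
  n <- nrow(hc$scores)
  if (k <= 1 || k > n) stop("k must be in (1, number of isolates]")
  tree_cl <- cutree(hc$hclust, k = k)
  centers <- do.call(rbind, lapply(split(seq_len(n), tree_cl), function(i)
    colMeans(hc$scores[i, , drop = FALSE])))
  before <- within_inertia(hc$scores, tree_cl)
  if (k < n) {
    km <- kmeans(hc$scores, centers = centers, iter.max = 100)
    cl <- setNames(km$cluster, rownames(hc$scores))
    after <- km$tot.withinss
    centers <- km$centers
  } else {
    cl <- tree_cl  # singleton clusters: consolidation is the identity
    after <- before
  }
  structure(list(k = k, tree_assignment = tree_cl, assignment = cl,
                 centers = centers, within_before = before,
                 within_after = after,
                 factor_map = hc$scores[, 1:2, drop = FALSE],
                 hclust = hc$hclust),
            class = "hcpc_result")
}

#' @method print hcpc_result
#' @param x object to print
#' @param ... unused
#' @export
print.hcpc_result <- function(x, ...) {
  cat(sprintf("hcpc_result: %d clusters; within-inertia %.3f -> %.3f after consolidation\n",
              x$k, x$within_before, x$within_after))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths derive from the merge heights; the text round-trips
#' through [ape::read.tree()] with identical topology.
#'
#' @param hc an `hc_result`, `hclust`, or `hcpc_result`
#' @param labels optional replacement leaf labels (must be unique)
#' @return Newick string
#' @export
export_tree <- function(hc, labels = NULL) {
  h <- if (inherits(hc, "hclust")) hc else hc$hclust
  if (!is.null(labels)) h$labels <- labels
  if (anyDuplicated(h$labels)) stop("duplicate labels")
  phy <- ape::as.phylo(h)
  ape::write.tree(phy)
}
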