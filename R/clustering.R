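#' Pairwise Euclidean distances
#'
#' Distance matrix for participant feature vectors. Features are used raw
#' (unstandardized): bets all live on the same 0--10 scale and standardizing
#' would erase the low-variance vs high-variance strategy distinction the
#' clusters are meant to expose.
#'
#' @param X an n x d numeric matrix with no missing values.
#' @return an n x n symmetric matrix with zero diagonal.
#' @export
mm_distances <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (anyNA(X))
    stop("missing values in feature matrix; apply as_mm_series() listwise ",
         "deletion before clustering")
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Hierarchical complete-linkage clustering of participants
#'
#' Agglomerative clustering with the complete-linkage criterion (the distance
#' between two clusters is the maximum pairwise distance between their
#' members), applied to either the 60-dimensional flattened bet vectors
#' (betting-strategy clusters, \code{feature = "bets"}) or the R-dimensional
#' per-round mBrier vectors (score-trajectory clusters,
#' \code{feature = "mbrier"}). Cuts at each requested k are produced by
#' undoing the last k-1 merges; cluster labels are renumbered by decreasing
#' cluster size (ties broken by smallest member index) so numbering is
#' reproducible.
#'
#' @param x an \code{mm_series} (for \code{feature = "bets"}), an
#'   \code{mm_scores} (for \code{feature = "mbrier"}), or a plain numeric
#'   matrix used as-is.
#' @param feature which feature matrix to build from \code{x}.
#' @param k integer vector of cut levels (default \code{c(2, 3)}, the two
#'   coarsest non-trivial partitions).
#' @return an object of class \code{mm_clust}: the underlying
#'   \code{\link[stats]{hclust}} tree, the feature matrix, and one
#'   \code{mm_assignment} per requested k.
#' @seealso \code{\link{mm_cut}}, \code{\link{cluster_profile}},
#'   \code{\link{dendrogram_newick}}
#' @export
mm_cluster <- function(x, feature = c("bets", "mbrier"), k = c(2, 3)) {
  feature <- match.arg(feature)
  X <- if (is.matrix(x)) x
       else if (inherits(x, "mm_series")) {
         if (feature != "bets")
           stop("feature 'mbrier' needs an mm_scores object (run mm_score first)")
         flatten_bets(x)
       } else if (inherits(x, "mm_scores")) {
         if (feature != "mbrier")
           stop("feature 'bets' needs an mm_series object")
         mbrier_matrix(x)
       } else stop("x must be an mm_series, mm_scores, or matrix")
  D <- mm_distances(X)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  if (any(k < 1 | k > nrow(X)))
    stop("k must lie in [1, ", nrow(X), "]")
  assignments <- lapply(k, function(kk) mm_cut(hc, kk, X))
  names(assignments) <- paste0("k", k)
  structure(list(hclust = hc, feature = feature, data = X, k = k,
                 assignments = assignments),
            class = "mm_clust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges of a complete-linkage tree; the resulting
#' connected components are the clusters. Labels are assigned by decreasing
#' cluster size, ties by smallest member index.
#'
#' @param tree an \code{mm_clust} or \code{\link[stats]{hclust}} object.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @param X optional feature matrix for cluster profiles (taken from the
#'   \code{mm_clust} object when available).
#' @return an object of class \code{mm_assignment}: \code{k}, named integer
#'   \code{labels}, \code{sizes}, and (when features are available)
#'   \code{profiles} with per-cluster columnwise means and SDs.
#' @export
mm_cut <- function(tree, k, X = NULL) {
  if (inherits(tree, "mm_clust")) {
    if (is.null(X)) X <- tree$data
    tree <- tree$hclust
  }
  if (!inherits(tree, "hclust")) stop("tree must be an mm_clust or hclust")
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  sizes <- tabulate(raw, nbins = k)
  first_member <- vapply(seq_len(k), function(l) which(raw == l)[1], 0L)
  new_order <- order(-sizes, first_member)
  relabel <- integer(k); relabel[new_order] <- seq_len(k)
  labels <- stats::setNames(relabel[raw], names(raw))
  out <- list(k = k, labels = labels,
              sizes = tabulate(labels, nbins = k))
  if (!is.null(X)) out$profiles <- cluster_profile(labels, X)
  structure(out, class = "mm_assignment")
}

#' Per-cluster feature profiles
#'
#' Columnwise means and standard deviations of the feature matrix within each
#' cluster: the numerical content of the usual radar-graph displays.
#'
#' @param labels integer cluster labels (1..k), one per row of \code{X}.
#' @param X the feature matrix the clustering was run on.
#' @return list with k x d matrices \code{mean} and \code{sd} (SD is 0 for
#'   singleton clusters).
#' @export
cluster_profile <- function(labels, X) {
  if (inherits(labels, "mm_assignment")) labels <- labels$labels
  X <- as.matrix(X)
  if (length(labels) != nrow(X)) stop("labels must cover the rows of X")
  k <- max(labels)
  mean_m <- do.call(rbind, lapply(seq_len(k), function(l)
    colMeans(X[labels == l, , drop = FALSE])))
  sd_m <- do.call(rbind, lapply(seq_len(k), function(l) {
    sub <- X[labels == l, , drop = FALSE]
    if (nrow(sub) < 2) rep(0, ncol(X)) else apply(sub, 2, stats::sd)
  }))
  rownames(mean_m) <- rownames(sd_m) <- paste0("cluster", seq_len(k))
  list(mean = mean_m, sd = sd_m)
}

#' @export
print.mm_clust <- function(x, ...) {
  cat(sprintf("mm_clust: complete-linkage tree over %d participants (%s features, d=%d)\n",
              nrow(x$data), x$feature, ncol(x$data)))
  for (a in x$assignments)
    cat(sprintf("  k=%d sizes: %s\n", a$k, paste(a$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
print.mm_assignment <- function(x, ...) {
  cat(sprintf("mm_assignment: k=%d, sizes %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
plot.mm_clust <- function(x, ...) {
  plot(x$hclust, labels = FALSE, hang = -1,
       main = sprintf("complete linkage (%s)", x$feature),
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Export a dendrogram as JSON
#'
#' Serialises the full merge history: for each agglomeration step the two
#' nodes merged (negative = leaf index, positive = earlier merge index, the
#' \code{hclust} convention), the complete-linkage merge height, and the size
#' of the merged cluster.
#'
#' @param tree \code{mm_clust} or \code{hclust}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to \code{path}.
#' @export
dendrogram_json <- function(tree, path = NULL) {
  if (inherits(tree, "mm_clust")) tree <- tree$hclust
  n <- length(tree$order)
  sizes <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    m <- tree$merge[i, ]
    sizes[i] <- sum(ifelse(m < 0, 1L, sizes[pmax(m, 1)]))
  }
  obj <- list(n_leaves = n,
              labels = tree$labels,
              merges = data.frame(node_a = tree$merge[, 1],
                                  node_b = tree$merge[, 2],
                                  height = tree$height,
                                  merged_size = sizes))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Export a dendrogram in Newick format
#'
#' Ultrametric tree with branch lengths derived from merge-height differences
#' (via \code{\link[ape]{as.phylo}}, which places each internal node at half
#' the merge height so tip-to-root path lengths are equal), for viewing in
#' standard tree tools.
#'
#' @inheritParams dendrogram_json
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  if (inherits(tree, "mm_clust")) tree <- tree$hclust
  if (is.null(tree$labels)) tree$labels <- paste0("p", seq_along(tree$order))
  phy <- ape::as.phylo(tree)
  if (!is.null(path)) { ape::write.tree(phy, file = path); return(invisible(path)) }
  ape::write.tree(phy)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items; 1 for
#' identical partitions (up to label renaming), ~0 for independent ones. Used
#' to quantify recovery of planted archetype structure in synthetic cohorts.
#'
#' @param a,b label vectors of equal length.
#' @return a single number (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
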