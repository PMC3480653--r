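#' Correlation-derived distance matrix
#'
#' Transforms a gene-gene correlation matrix into a dissimilarity for
#' hierarchical clustering: `d = 1 - r` (default, preserves the sign so
#' anti-correlated genes are maximally distant) or `d = 1 - |r|`.
#'
#' @param corr Valid correlation matrix (symmetric, unit diagonal, |r| <= 1).
#' @param mode `"one_minus_r"` or `"one_minus_abs_r"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(corr, mode = c("one_minus_r", "one_minus_abs_r")) {
  mode <- match.arg(mode)
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("corr must have unit diagonal")
  if (any(abs(corr) > 1 + 1e-8)) stop("corr entries must be in [-1, 1]")
  d <- if (mode == "one_minus_r") 1 - corr else 1 - abs(corr)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of genes
#'
#' Wraps [stats::hclust()] with input validation and a fixed deterministic
#' ordering: items are sorted lexicographically before clustering so merge
#' ties are always broken toward the lexicographically smallest pair.
#'
#' @param dist_matrix Symmetric non-negative distance matrix with zero
#'   diagonal and >= 2 items (row/column names are the gene labels).
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`.
#' @return A `linkage_tree`: `merge` records, `height` per merge (length
#'   n_genes - 1, non-decreasing), leaf `labels`, and the underlying `hclust`
#'   object.
#' @export
hierarchical_cluster <- function(dist_matrix, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist_matrix)
  if (nrow(d) < 2L) stop("need >= 2 items to cluster")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("g", seq_len(nrow(d)))
  }
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels,
                 linkage = linkage, hclust = hc),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("linkage_tree:", length(x$labels), "leaves,", x$linkage, "linkage\n")
  cat("merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, 1 <= k <= n_genes.
#' @return Named integer vector mapping each gene to a cluster id.
#' @export
cluster_membership <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(tree$hclust, k = k)
}

#' Export a linkage tree as a Newick string
#'
#' Branch lengths are derived from the merge heights via
#' [ape::as.phylo()].
#'
#' @param tree A `linkage_tree`.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when writing to file.
#' @export
as_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Write the merge table of a linkage tree as TSV
#'
#' @param tree A `linkage_tree`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_merge_table <- function(tree, file) {
  stopifnot(inherits(tree, "linkage_tree"))
  tab <- data.frame(node_a = tree$merge[, 1], node_b = tree$merge[, 2],
                    height = tree$height)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
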