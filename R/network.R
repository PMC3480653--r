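#' Pearson product-moment correlation with strict input checks
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant
#'   (a constant vector leaves the correlation undefined and raises an error
#'   rather than returning 0).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: input vector is constant")
  }
  stats::cor(x, y, method = "pearson")
}

#' Classify a correlation into a network edge class
#'
#' Thresholds follow the network figures' legend: strong for |r| >= 0.9,
#' moderate for 0.8 <= |r| < 0.9, none otherwise.  Both thresholds are
#' inclusive on their lower bound.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @param strong_thr,moderate_thr Class boundaries, 0 < moderate < strong <= 1.
#' @return Character vector in `c("strong", "moderate", "none")`.
#' @export
classify_edge <- function(r, strong_thr = 0.9, moderate_thr = 0.8) {
  if (!(moderate_thr > 0 && moderate_thr < strong_thr && strong_thr <= 1)) {
    stop("thresholds must satisfy 0 < moderate_thr < strong_thr <= 1")
  }
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  ifelse(abs(r) >= strong_thr, "strong",
         ifelse(abs(r) >= moderate_thr, "moderate", "none"))
}

#' Flag outlying samples by robust per-gene z-scores
#'
#' Within each group and gene, the robust z-score
#' |value - median| / (1.4826 * MAD) is computed; a sample is flagged when any
#' of its genes exceeds `z_max`.  Genes with zero MAD in a group are skipped
#' with a warning.  Flagging never removes samples; use [drop_samples()] to
#' exclude flagged ids explicitly.
#'
#' @param data An `expression_dataset` with >= 5 samples per group.
#' @param z_max Robust z threshold (default 5, deliberately conservative).
#' @param log_transform Screen log(values) instead of raw values; advisable
#'   for strongly right-skewed expression data, where raw-scale robust z
#'   flags legitimate upper-tail samples.
#' @return An `outlier_report`: data frame `evidence` (sample_id, group, gene,
#'   value, robust_z) and `flagged` sample ids.
#' @export
flag_outliers <- function(data, z_max = 5, log_transform = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  tab <- table(data$group)
  if (any(tab < 5)) {
    stop("each group needs >= 5 samples for robust outlier screening; too small: ",
         paste(names(tab)[tab < 5], collapse = ", "))
  }
  vals <- data$values
  if (log_transform) {
    if (any(vals <= 0)) stop("log_transform requires strictly positive values")
    vals <- log(vals)
  }
  ev <- list()
  skipped <- character(0)
  for (g in names(tab)) {
    idx <- data$group == g
    for (gene in data$genes) {
      v <- vals[idx, gene]
      m <- median(v)
      mad_v <- stats::mad(v)  # already scaled by 1.4826
      if (mad_v == 0) {
        skipped <- c(skipped, paste0(g, "/", gene))
        next
      }
      z <- abs(v - m) / mad_v
      hit <- which(z > z_max)
      if (length(hit)) {
        ev[[length(ev) + 1L]] <- data.frame(
          sample_id = data$sample_id[idx][hit], group = g, gene = gene,
          value = v[hit], robust_z = z[hit], row.names = NULL)
      }
    }
  }
  if (length(skipped)) {
    warning("zero MAD, gene skipped in outlier screen: ",
            paste(skipped, collapse = ", "))
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(sample_id = character(0), group = character(0),
               gene = character(0), value = numeric(0), robust_z = numeric(0))
  structure(list(evidence = evidence,
                 flagged = unique(evidence$sample_id),
                 z_max = z_max),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report:", length(x$flagged), "sample(s) flagged at robust z >",
      x$z_max, "\n")
  if (nrow(x$evidence)) print(x$evidence)
  invisible(x)
}

#' Build a per-group thresholded co-expression network
#'
#' Computes all unordered gene-pair Pearson correlations within one group and
#' classifies each pair (strong/moderate/none).  Groups smaller than `min_n`
#' are refused (returned as an explicitly skipped network) because the
#' correlation estimates would be unreliable, mirroring the exclusion of the
#' n = 19 at-risk group in the original analysis.
#'
#' @param data An `expression_dataset`.
#' @param group Group label to subset.
#' @param strong_thr,moderate_thr Edge class thresholds, see [classify_edge()].
#' @param min_n Minimum group size (default 20).
#' @param log_transform Compute correlations on log(values) instead of raw
#'   values (default FALSE; the scale is left to the analyst).
#' @return A `correlation_network`: `genes`, symmetric `corr` matrix with unit
#'   diagonal, `edges` data frame (gene_a < gene_b lexicographically, r,
#'   class), `n_samples`, `group`; or a skipped record with `skipped = TRUE`
#'   and a `reason` when n < min_n.
#' @export
build_network <- function(data, group, strong_thr = 0.9, moderate_thr = 0.8,
                          min_n = 20, log_transform = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!group %in% data$group) stop("group not present: ", group)
  idx <- data$group == group
  n <- sum(idx)
  if (n < min_n) {
    return(structure(list(group = group, genes = data$genes, corr = NULL,
                          edges = NULL, n_samples = n, skipped = TRUE,
                          reason = sprintf(
                            "group %s has n = %d < min_n = %d: too small to estimate correlation coefficients reliably",
                            group, n, min_n)),
                     class = "correlation_network"))
  }
  v <- data$values[idx, , drop = FALSE]
  if (log_transform) {
    if (any(v <= 0)) stop("log_transform requires strictly positive values")
    v <- log(v)
  }
  const <- apply(v, 2, sd) == 0
  if (any(const)) {
    stop("constant gene column(s) in group ", group, ": ",
         paste(data$genes[const], collapse = ", "))
  }
  corr <- stats::cor(v, method = "pearson")
  diag(corr) <- 1
  genes_sorted <- sort(data$genes)
  pairs <- t(combn(genes_sorted, 2))
  r <- corr[cbind(pairs[, 1], pairs[, 2])]
  edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], r = r,
                      class = classify_edge(r, strong_thr, moderate_thr),
                      stringsAsFactors = FALSE)
  structure(list(group = group, genes = data$genes, corr = corr, edges = edges,
                 n_samples = n, skipped = FALSE,
                 thresholds = c(strong = strong_thr, moderate = moderate_thr)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("correlation_network [skipped]:", x$reason, "\n")
  } else {
    cat("correlation_network:", x$group, "(n =", x$n_samples, ")\n")
    print(table(factor(x$edges$class, levels = c("strong", "moderate", "none"))))
  }
  invisible(x)
}

#' Compare two classified co-expression networks
#'
#' Deterministic set arithmetic on the classified edge lists of two networks
#' over the same gene set: per-class edge counts, edges gained/lost (class
#' none in one network, an edge in the other), per-gene degree, and mean |r|.
#'
#' @param a,b `correlation_network` objects over identical gene sets.
#' @return A `network_comparison` list.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "correlation_network"), inherits(b, "correlation_network"))
  if (isTRUE(a$skipped) || isTRUE(b$skipped)) stop("cannot compare a skipped network")
  if (!setequal(a$genes, b$genes)) {
    stop("gene sets differ; only in first: ",
         paste(setdiff(a$genes, b$genes), collapse = ", "),
         "; only in second: ", paste(setdiff(b$genes, a$genes), collapse = ", "))
  }
  key <- function(e) paste(e$gene_a, e$gene_b, sep = "|")
  ea <- a$edges
  eb <- b$edges
  stopifnot(identical(key(ea), key(eb)))  # same lexicographic pair order
  present_a <- ea$class != "none"
  present_b <- eb$class != "none"
  gained <- eb[!present_a & present_b, c("gene_a", "gene_b", "r", "class")]
  lost <- ea[present_a & !present_b, c("gene_a", "gene_b", "r", "class")]
  counts <- function(e) table(factor(e$class, levels = c("strong", "moderate", "none")))
  degree <- function(e) {
    pres <- e[e$class != "none", ]
    tab <- table(factor(c(pres$gene_a, pres$gene_b), levels = sort(a$genes)))
    setNames(as.vector(tab, mode = "integer"), names(tab))
  }
  structure(list(
    groups = c(a$group, b$group),
    counts_a = counts(ea), counts_b = counts(eb),
    gained = gained, lost = lost,
    degree_a = degree(ea), degree_b = degree(eb),
    mean_abs_r_a = mean(abs(ea$r)), mean_abs_r_b = mean(abs(eb$r))),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("network comparison:", x$groups[1], "vs", x$groups[2], "\n")
  cat(sprintf("mean |r|: %.3f vs %.3f\n", x$mean_abs_r_a, x$mean_abs_r_b))
  cat("edges gained:", nrow(x$gained), " lost:", nrow(x$lost), "\n")
  invisible(x)
}

#' Write a network to disk (edge TSV, correlation CSV, GraphML, DOT)
#'
#' Graph exports contain only classified edges (|r| above the moderate
#' threshold), weighted by r.
#'
#' @param net A non-skipped `correlation_network`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "correlation_network"))
  if (isTRUE(net$skipped)) stop("cannot write a skipped network: ", net$reason)
  edge_file <- paste0(prefix, "_edges.tsv")
  e <- net$edges
  e$group <- net$group
  utils::write.table(e, edge_file, sep = "\t", quote = FALSE, row.names = FALSE)
  corr_file <- paste0(prefix, "_corr.csv")
  utils::write.csv(net$corr, corr_file)
  pres <- net$edges[net$edges$class != "none", , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    pres[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = sort(net$genes)))
  igraph::E(g)$weight <- pres$r
  igraph::E(g)$class <- pres$class
  graphml_file <- paste0(prefix, ".graphml")
  dot_file <- paste0(prefix, ".dot")
  igraph::write_graph(g, graphml_file, format = "graphml")
  igraph::write_graph(g, dot_file, format = "dot")
  invisible(c(edge_file, corr_file, graphml_file, dot_file))
}
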