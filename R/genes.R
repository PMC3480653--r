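#' The 13-gene immune panel
#'
#' Canonical ordering of the thirteen immune genes analyzed throughout the
#' package: T lymphocyte genes (CD3G, CTLA4), B lymphocyte genes (CD19, CD20),
#' myeloid-related genes (CD11b, TLR9, ARG1), and six members of the S100
#' family implicated in immune regulation.
#'
#' @return Character vector of 13 gene names.
#' @export
#' @examples
#' t1d_gene_panel()
t1d_gene_panel <- function() {
  c("ARG1", "CD19", "CD3G", "CTLA4", "CD11b", "CD20",
    "S100A10", "S100A11", "S100A13", "S100A6", "S100A8", "S100A9", "TLR9")
}

#' Specify a correlated gene block
#'
#' A block is a set of genes sharing a common within-block correlation on the
#' log-expression scale, e.g. the two T-cell genes or the S100 family.  The
#' implied equicorrelation matrix must be positive definite, which for a block
#' of m genes requires within_rho > -1/(m-1).
#'
#' @param block_name One of `"t_cell"`, `"b_cell"`, `"myeloid"`, `"s100"`.
#' @param genes Character vector of gene names (non-empty).
#' @param within_rho Common correlation between block members, |rho| < 1.
#' @param mean_log_expr Mean of log-expression, recycled per gene.
#' @param sd_log_expr SD of log-expression (> 0), recycled per gene.
#' @return An object of class `gene_block`.
#' @export
gene_block <- function(block_name, genes, within_rho,
                       mean_log_expr = 0, sd_log_expr = 1) {
  block_name <- match.arg(block_name, c("t_cell", "b_cell", "myeloid", "s100"))
  if (length(genes) < 1L) stop("block '", block_name, "': genes must be non-empty")
  if (anyDuplicated(genes)) stop("block '", block_name, "': duplicated gene names")
  if (abs(within_rho) >= 1) stop("block '", block_name, "': |within_rho| must be < 1")
  m <- length(genes)
  if (m > 1L && within_rho <= -1 / (m - 1)) {
    stop("block '", block_name, "': within_rho = ", within_rho,
         " makes the block correlation matrix non-positive-definite ",
         "(need within_rho > ", signif(-1 / (m - 1), 3), " for ", m, " genes)")
  }
  mean_log_expr <- rep_len(mean_log_expr, m)
  sd_log_expr <- rep_len(sd_log_expr, m)
  if (any(sd_log_expr <= 0)) stop("block '", block_name, "': sd_log_expr must be > 0")
  structure(list(block_name = block_name, genes = genes,
                 within_rho = within_rho,
                 mean_log_expr = setNames(mean_log_expr, genes),
                 sd_log_expr = setNames(sd_log_expr, genes)),
            class = "gene_block")
}

#' Default gene blocks for the 13-gene panel
#'
#' Lineage blocks with strong within-block co-expression: the T-cell and
#' B-cell marker pairs are tightly coupled (rho = 0.92, both members report
#' the same cell lineage), the myeloid and S100 blocks somewhat less so
#' (rho = 0.85).  Log-expression is standard normal per gene (several-fold
#' between-subject variation, typical of relative qRT-PCR quantities).
#'
#' @return List of four `gene_block` objects covering the panel.
#' @export
default_gene_blocks <- function() {
  list(
    gene_block("t_cell", c("CD3G", "CTLA4"), within_rho = 0.92),
    gene_block("b_cell", c("CD19", "CD20"), within_rho = 0.92),
    gene_block("myeloid", c("CD11b", "TLR9", "ARG1"), within_rho = 0.85),
    gene_block("s100",
               c("S100A10", "S100A11", "S100A13", "S100A6", "S100A8", "S100A9"),
               within_rho = 0.85)
  )
}

#' Reported long-term T1D interaction coefficients
#'
#' The published elastic-net coefficient table for the long-term T1D versus
#' healthy comparison on this 13-gene panel: main effects on the diagonal,
#' pairwise interaction coefficients in the upper triangle, and significance
#' marks (`"*"` p < 0.05, `"**"` p < 0.0005).  Used as reference input for
#' worked examples and as plantable ground truth for the synthetic generator.
#'
#' @return List with `coefficients` (13 x 13 numeric matrix, upper triangle +
#'   diagonal) and `marks` (character matrix of the same shape).
#' @export
#' @examples
#' tab <- reported_lt_coefficients()
#' tab$coefficients["CD3G", "CD20"]   # 0.21
#' odds_ratio(tab$coefficients["CD3G", "CD20"])
reported_lt_coefficients <- function() {
  genes <- t1d_gene_panel()
  co <- matrix(0, 13, 13, dimnames = list(genes, genes))
  mk <- matrix("", 13, 13, dimnames = list(genes, genes))
  set_entry <- function(a, b, v, m = "") {
    co[a, b] <<- v
    mk[a, b] <<- m
  }
  set_entry("ARG1", "CD3G", 0.07)
  set_entry("ARG1", "S100A13", 0.03)
  set_entry("ARG1", "S100A6", 0.22, "*")
  set_entry("ARG1", "S100A8", 0.01)
  set_entry("ARG1", "S100A9", -0.21, "*")
  set_entry("CD3G", "CD20", 0.21, "*")
  set_entry("CD3G", "S100A13", 0.06)
  set_entry("CTLA4", "S100A13", 0.03)
  set_entry("CD11b", "S100A10", 0.02)
  set_entry("CD20", "S100A13", 0.04)
  set_entry("CD20", "S100A9", -0.15)
  set_entry("S100A10", "S100A13", -0.05)
  set_entry("S100A10", "TLR9", 0.11)
  set_entry("S100A13", "S100A13", -0.62, "**")
  set_entry("S100A13", "S100A6", 0.09)
  set_entry("S100A13", "S100A9", -0.11)
  set_entry("S100A13", "TLR9", 0.01)
  list(coefficients = co, marks = mk)
}

#' Significant reported coefficients as a plantable set
#'
#' The subset of [reported_lt_coefficients()] flagged significant in the
#' original analysis, in the coefficient-set format accepted by
#' [synthetic_config()] `planted_beta`: one main effect (S100A13, -0.62) and
#' three interactions (ARG1:S100A6 0.22, ARG1:S100A9 -0.21, CD3G:CD20 0.21).
#'
#' @return List with `main` and `pair` named numeric vectors plus `age = 0`.
#' @export
reported_significant_coefficients <- function() {
  list(
    main = c(S100A13 = -0.62),
    pair = c("ARG1:S100A6" = 0.22, "ARG1:S100A9" = -0.21, "CD3G:CD20" = 0.21),
    age = 0
  )
}
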