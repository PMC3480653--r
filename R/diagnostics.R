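#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Samples are binned into `g` groups by deciles of fitted probability (tied
#' probabilities are never split across bins); the statistic sums
#' `(O - E)^2 / (E (1 - E / n_g))` over bins for the event class, with
#' `df = g - 2` and a chi-square upper-tail p-value.  Bins whose expected
#' event count is 0 are merged with their neighbor (df adjusted, with a
#' warning).
#'
#' @param fitted_probs Fitted probabilities in (0, 1).
#' @param y 0/1 outcomes.
#' @param g Number of bins (default 10); requires n >= 2g.
#' @return List with `statistic`, `df`, `p_value`, and the per-bin `table`.
#' @export
hosmer_lemeshow <- function(fitted_probs, y, g = 10) {
  n <- length(y)
  if (length(fitted_probs) != n) stop("length mismatch")
  if (n < 2 * g) stop("need n >= 2g observations for ", g, " bins")
  if (any(fitted_probs <= 0 | fitted_probs >= 1)) {
    stop("fitted probabilities must lie strictly in (0, 1)")
  }
  breaks <- unique(quantile(fitted_probs, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 3L) stop("fitted probabilities too tied to form >= 2 bins")
  bin <- cut(fitted_probs, breaks = breaks, include.lowest = TRUE)
  O <- tapply(y, bin, sum)
  E <- tapply(fitted_probs, bin, sum)
  ng <- tapply(y, bin, length)
  keep <- !is.na(ng)
  O <- O[keep]; E <- E[keep]; ng <- ng[keep]

  # merge bins with zero expected events into the neighbor above
  merged <- FALSE
  i <- 1L
  while (i <= length(E)) {
    if (E[i] < .Machine$double.eps * ng[i] || (ng[i] - E[i]) < .Machine$double.eps * ng[i]) {
      j <- if (i < length(E)) i + 1L else i - 1L
      if (j < 1L) break
      O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; ng[j] <- ng[j] + ng[i]
      O <- O[-i]; E <- E[-i]; ng <- ng[-i]
      merged <- TRUE
    } else {
      i <- i + 1L
    }
  }
  if (merged) warning("bins with degenerate expected counts were merged; df adjusted")
  nbins <- length(E)
  if (nbins < 3L) stop("fewer than 3 usable bins after merging")
  statistic <- sum((O - E)^2 / (E * (1 - E / ng)))
  df <- nbins - 2L
  p_value <- pchisq(statistic, df = df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p_value = p_value,
       table = data.frame(n = as.vector(ng), observed = as.vector(O),
                          expected = as.vector(E)))
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is computed from average ranks with the standard tie correction (tied
#' case/control scores count 1/2 concordant); the ROC curve is built by a
#' threshold sweep over the unique scores, anchored at (0, 0) and (1, 1).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param y 0/1 outcomes; both classes must be present.
#' @return List with `auc` and `roc` (data frame of `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4, 0.7, 0.1), c(1, 1, 0, 0))$auc  # 0.75
roc_auc <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)  # average ranks handle ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y == 1 & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(y == 0 & scores >= t) / n0, numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- unique(roc[order(roc$fpr, roc$tpr), ])
  rownames(roc) <- NULL
  list(auc = auc, roc = roc)
}

#' Combined model diagnostics
#'
#' Hosmer-Lemeshow goodness of fit plus ROC/AUC discrimination for fitted
#' case probabilities.
#'
#' @param fitted_probs Fitted probabilities in (0, 1).
#' @param y 0/1 outcomes.
#' @param g Hosmer-Lemeshow bin count.
#' @return A `diagnostics_report`: `hl_statistic`, `hl_df`, `hl_p`,
#'   `roc_points`, `auc`.
#' @export
model_diagnostics <- function(fitted_probs, y, g = 10) {
  hl <- hosmer_lemeshow(fitted_probs, y, g = g)
  ra <- roc_auc(fitted_probs, y)
  structure(list(hl_statistic = hl$statistic, hl_df = hl$df,
                 hl_p = hl$p_value, hl_table = hl$table,
                 roc_points = ra$roc, auc = ra$auc),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.3f\n",
              x$hl_statistic, x$hl_df, x$hl_p))
  cat(sprintf("ROC AUC = %.3f\n", x$auc))
  invisible(x)
}

#' Write diagnostics to disk (JSON summary + ROC points TSV)
#'
#' @param diag A `diagnostics_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_diagnostics <- function(diag, prefix) {
  stopifnot(inherits(diag, "diagnostics_report"))
  f1 <- paste0(prefix, "_diagnostics.json")
  f2 <- paste0(prefix, "_roc.tsv")
  jsonlite::write_json(list(hl_statistic = diag$hl_statistic,
                            hl_df = diag$hl_df, hl_p = diag$hl_p,
                            auc = diag$auc),
                       f1, auto_unbox = TRUE, digits = NA)
  utils::write.table(diag$roc_points, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f1, f2))
}
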