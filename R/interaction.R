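#' Expand an expression dataset into an interaction design
#'
#' Builds the design matrix of the cross-group logistic model: an intercept,
#' one main-effect column per gene, one column per unordered gene pair holding
#' the elementwise product of the two raw expression columns, and optionally
#' age.  Main and pair columns (the penalized block) are standardized to mean
#' 0, variance 1 after the products are formed; the intercept and age are
#' left unstandardized and unpenalized.  For 13 genes this yields
#' 1 + 13 + 78 + 1 = 93 columns.
#'
#' @param data An `expression_dataset`.
#' @param case_group Group coded Y = 1.
#' @param control_group Group coded Y = 0.  Samples from other groups are
#'   dropped.
#' @param include_age Include the (unpenalized) age column (default TRUE).
#' @return An `interaction_design`: standardized matrix `X`, outcome `y`, raw
#'   penalized columns `X_raw`, standardization record (`center`, `scale`),
#'   `penalty` indicator per column, `genes`, and column `labels`.
#' @export
expand_design <- function(data, case_group, control_group, include_age = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  for (g in c(case_group, control_group)) {
    if (sum(data$group == g) < 2L) stop("group absent or has < 2 samples: ", g)
  }
  if (identical(case_group, control_group)) stop("case and control groups must differ")
  keep <- data$group %in% c(case_group, control_group)
  v <- data$values[keep, , drop = FALSE]
  y <- as.numeric(data$group[keep] == case_group)
  age <- data$age[keep]
  genes <- data$genes

  const <- apply(v, 2, sd) == 0
  if (any(const)) {
    stop("constant expression column(s) break standardization: ",
         paste(genes[const], collapse = ", "))
  }

  pair_idx <- combn(seq_along(genes), 2)
  pair_names <- paste(genes[pair_idx[1, ]], genes[pair_idx[2, ]], sep = ":")
  X_pairs <- v[, pair_idx[1, ], drop = FALSE] * v[, pair_idx[2, ], drop = FALSE]
  colnames(X_pairs) <- pair_names

  X_raw <- cbind(v, X_pairs)
  center <- colMeans(X_raw)
  scale <- apply(X_raw, 2, sd)
  X_std <- sweep(sweep(X_raw, 2, center), 2, scale, "/")

  X <- cbind(`(Intercept)` = 1, X_std)
  penalty <- c(0, rep(1, ncol(X_std)))
  if (include_age) {
    X <- cbind(X, age = age)
    penalty <- c(penalty, 0)
  }
  structure(list(X = X, y = y, X_raw = X_raw, age = if (include_age) age else NULL,
                 center = center, scale = scale, penalty = penalty,
                 genes = genes, main_names = genes, pair_names = pair_names,
                 labels = colnames(X), include_age = include_age,
                 case_group = case_group, control_group = control_group,
                 sample_id = data$sample_id[keep]),
            class = "interaction_design")
}

#' @export
print.interaction_design <- function(x, ...) {
  cat("interaction_design:", length(x$y), "samples x", ncol(x$X), "columns (",
      sum(x$y), "cases /", sum(1 - x$y), "controls )\n")
  invisible(x)
}

stable_binomial_loglik <- function(eta, y) {
  # sum_i y_i eta_i - log(1 + exp(eta_i)), overflow-safe
  sum(y * eta - ifelse(eta > 35, eta, ifelse(eta < -30, exp(eta), log1p(exp(eta)))))
}

#' Penalized binomial log-likelihood
#'
#' The elastic-net objective maximized by the solver: the binomial
#' log-likelihood minus `lambda (1 - alpha) / 2` times the sum of squared
#' penalized coefficients minus `lambda alpha` times the sum of their absolute
#' values.  Only main-effect and interaction coefficients are penalized; the
#' intercept and age are not.
#'
#' @param beta Coefficient vector on the design (standardized) scale, one
#'   entry per design column.
#' @param design An `interaction_design` (or list with `X` and `penalty`).
#' @param y Outcome vector (default the design's own).
#' @param alpha Elastic-net mixing constant in (0, 1\].
#' @param lambda Penalty weight >= 0.
#' @return Scalar objective value.
#' @export
penalized_loglik <- function(beta, design, y = design$y, alpha, lambda) {
  check_alpha_lambda(alpha, lambda)
  X <- design$X
  if (length(beta) != ncol(X)) stop("beta length must equal number of design columns")
  pen <- design$penalty > 0
  eta <- drop(X %*% beta)
  ll <- stable_binomial_loglik(eta, y)
  ll - lambda * (1 - alpha) / 2 * sum(beta[pen]^2) - lambda * alpha * sum(abs(beta[pen]))
}

check_alpha_lambda <- function(alpha, lambda) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  invisible(TRUE)
}

#' Smallest penalty weight that zeroes all penalized coefficients
#'
#' The null model (unpenalized columns only: intercept and, if present, age)
#' is fitted first; `lambda_max` is the largest absolute score-function entry
#' over penalized columns at that null fit, divided by alpha.  For
#' `lambda >= lambda_max` every penalized coefficient of the elastic-net
#' optimum is exactly 0.
#'
#' @param design An `interaction_design`.
#' @param alpha Elastic-net mixing constant in (0, 1].
#' @param y Outcome (default the design's own).
#' @return Scalar lambda_max.
#' @export
lambda_max <- function(design, alpha, y = design$y) {
  check_alpha_lambda(alpha, 1)
  X <- design$X
  pen <- design$penalty > 0
  X0 <- X[, !pen, drop = FALSE]
  fit0 <- stats::glm.fit(X0, y, family = stats::binomial())
  p0 <- fit0$fitted.values
  grad <- drop(crossprod(X[, pen, drop = FALSE], y - p0))
  max(abs(grad)) / alpha
}

#' Low-level elastic-net logistic solver
#'
#' Cyclic coordinate descent on the penalized binomial likelihood with IRLS
#' working responses and a step-halving safeguard that makes the objective
#' non-decreasing across outer iterations.  Exposed for small hand-built
#' problems; [fit_elastic_net()] is the high-level interface.
#'
#' @param X Design matrix including any intercept column.
#' @param y 0/1 outcome with both classes present.
#' @param penalty 0/1 indicator per column (0 = unpenalized).
#' @param alpha,lambda Elastic-net hyperparameters.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Sweep cap.
#' @param beta_init Optional warm start.
#' @return List with `beta`, `converged`, `sweeps`, `objective`,
#'   `objective_path`.
#' @export
enet_logistic <- function(X, y, penalty, alpha, lambda, tol = 1e-7,
                          max_iter = 1e4, beta_init = NULL) {
  check_alpha_lambda(alpha, lambda)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot fit")
  if (length(penalty) != ncol(X)) stop("penalty must have one entry per column")
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  res <- enet_cd_fit(X, as.numeric(y), as.numeric(penalty), alpha, lambda,
                     as.numeric(beta_init), tol, as.integer(max_iter))
  res$beta <- setNames(drop(res$beta), colnames(X))
  res
}

#' Fit the elastic-net penalized interaction logistic model
#'
#' @param design An `interaction_design` from [expand_design()].
#' @param alpha Elastic-net mixing constant in (0, 1].
#' @param lambda Penalty weight >= 0.
#' @param tol,max_iter Convergence controls (see [enet_logistic()]).
#' @param beta_init Optional warm start on the standardized scale.
#' @return An `interaction_fit`: coefficients on the original scale (`beta0`,
#'   `beta_main`, `beta_pair`, `beta_age`), standardized-scale coefficients
#'   `beta_std`, the `active_set` (penalized columns with nonzero
#'   coefficient), `alpha`, `lambda`, fitted binomial `deviance`, and a
#'   `converged` flag.  Inactive coefficients are exactly 0.
#' @export
fit_elastic_net <- function(design, alpha, lambda, tol = 1e-7, max_iter = 1e4,
                            beta_init = NULL) {
  stopifnot(inherits(design, "interaction_design"))
  res <- enet_logistic(design$X, design$y, design$penalty, alpha, lambda,
                       tol = tol, max_iter = max_iter, beta_init = beta_init)
  if (!res$converged) {
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  }
  beta_std <- res$beta
  pen_names <- c(design$main_names, design$pair_names)
  # flush numerical dust so the inactive set is exactly zero
  dust <- pen_names[abs(beta_std[pen_names]) < 1e-12]
  beta_std[dust] <- 0
  b_pen_std <- beta_std[pen_names]
  b_pen <- b_pen_std / design$scale[pen_names]
  beta0 <- beta_std[["(Intercept)"]] - sum(b_pen_std * design$center[pen_names] / design$scale[pen_names])
  beta_age <- if (design$include_age) beta_std[["age"]] else NA_real_
  eta <- drop(design$X %*% beta_std)
  dev <- -2 * stable_binomial_loglik(eta, design$y)
  structure(list(
    beta0 = beta0,
    beta_main = b_pen[design$main_names],
    beta_pair = b_pen[design$pair_names],
    beta_age = beta_age,
    beta_std = beta_std,
    active_set = pen_names[b_pen_std != 0],
    alpha = alpha, lambda = lambda,
    deviance = dev,
    converged = res$converged,
    sweeps = res$sweeps,
    objective = res$objective,
    objective_path = res$objective_path,
    genes = design$genes,
    include_age = design$include_age,
    case_group = design$case_group,
    control_group = design$control_group),
    class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("interaction_fit: %s vs %s, alpha = %.3g, lambda = %.4g\n",
              x$case_group, x$control_group, x$alpha, x$lambda))
  cat(sprintf("deviance %.2f, %d active penalized coefficient(s)%s\n",
              x$deviance, length(x$active_set),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$active_set)) {
    est <- c(x$beta_main, x$beta_pair)[x$active_set]
    print(signif(est, 3))
  }
  invisible(x)
}

#' Fitted case probabilities of an interaction fit
#'
#' @param object An `interaction_fit`.
#' @param design The `interaction_design` it was fitted on (or a compatible
#'   one).
#' @param ... Unused.
#' @return Vector of fitted P(Y = 1).
#' @export
predict.interaction_fit <- function(object, design, ...) {
  plogis(drop(design$X %*% object$beta_std))
}

#' Select elastic-net hyperparameters by leave-one-out cross-validation
#'
#' For every (alpha, lambda) grid cell, n fits are performed each leaving one
#' sample out (the penalized block is re-standardized on each training set),
#' and the LOO deviance -2 * sum of held-out log-likelihoods is recorded.
#' The minimizing cell is selected; exact ties are broken toward larger
#' lambda, then larger alpha (the sparser model).  Cells where any inner fit
#' fails are marked invalid and excluded.
#'
#' @param design An `interaction_design` with n >= 10.
#' @param alpha_grid Alphas to scan (default 0.1, 0.2, ..., 1.0).
#' @param n_lambda Number of lambda values per alpha (default 50),
#'   log-spaced from lambda_max down to `lambda_max * lambda_min_ratio`.
#' @param lambda_min_ratio Path floor ratio (default 1e-4).
#' @param lambda_path Optional explicit lambda vector used for every alpha
#'   (overrides `n_lambda`/`lambda_min_ratio`).
#' @param tol,max_iter Convergence controls for the inner fits.
#' @return A `cv_result`: `grid` data frame (alpha, lambda, deviance,
#'   n_failed, valid), `best_alpha`, `best_lambda`, `best_deviance`, and the
#'   tie-break `rule`.
#' @export
loocv_select <- function(design, alpha_grid = seq(0.1, 1, by = 0.1),
                         n_lambda = 50, lambda_min_ratio = 1e-4,
                         lambda_path = NULL, tol = 1e-6, max_iter = 5000) {
  stopifnot(inherits(design, "interaction_design"))
  n <- length(design$y)
  if (n < 10L) stop("LOOCV needs n >= 10")
  y <- design$y
  Xr <- design$X_raw
  age <- design$age
  p_pen <- ncol(Xr)

  paths <- lapply(alpha_grid, function(a) {
    if (!is.null(lambda_path)) {
      sort(lambda_path, decreasing = TRUE)
    } else {
      lm <- lambda_max(design, a)
      exp(seq(log(lm), log(lm * lambda_min_ratio), length.out = n_lambda))
    }
  })
  L <- length(paths[[1]])
  A <- length(alpha_grid)
  ll_held <- array(0, dim = c(A, L))
  failed <- array(0L, dim = c(A, L))

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xtr_raw <- Xr[tr, , drop = FALSE]
    ctr <- colMeans(Xtr_raw)
    str_ <- apply(Xtr_raw, 2, sd)
    if (any(str_ == 0)) {
      failed[, ] <- failed[, ] + 1L
      next
    }
    Xtr <- sweep(sweep(Xtr_raw, 2, ctr), 2, str_, "/")
    Xtr <- cbind(1, Xtr)
    penalty <- c(0, rep(1, p_pen))
    if (design$include_age) {
      Xtr <- cbind(Xtr, age[tr])
      penalty <- c(penalty, 0)
    }
    x_held <- c(1, (Xr[i, ] - ctr) / str_, if (design$include_age) age[i])
    ytr <- y[tr]
    for (ai in seq_len(A)) {
      res <- tryCatch(
        enet_cd_path(Xtr, ytr, penalty, alpha_grid[ai], paths[[ai]], tol,
                     as.integer(max_iter)),
        error = function(e) NULL)
      if (is.null(res)) {
        failed[ai, ] <- failed[ai, ] + 1L
        next
      }
      eta_i <- drop(x_held %*% res$beta)
      p_i <- pmin(pmax(plogis(eta_i), 1e-12), 1 - 1e-12)
      ll_held[ai, ] <- ll_held[ai, ] +
        y[i] * log(p_i) + (1 - y[i]) * log(1 - p_i)
    }
  }

  grid <- do.call(rbind, lapply(seq_len(A), function(ai) {
    data.frame(alpha = alpha_grid[ai], lambda = paths[[ai]],
               deviance = -2 * ll_held[ai, ], n_failed = failed[ai, ])
  }))
  grid$valid <- grid$n_failed == 0L
  if (!any(grid$valid)) stop("all LOOCV grid cells failed")
  valid <- grid[grid$valid, ]
  dmin <- min(valid$deviance)
  cand <- valid[valid$deviance <= dmin + 1e-10, ]
  cand <- cand[order(-cand$lambda, -cand$alpha), ]
  best <- cand[1, ]
  structure(list(grid = grid, best_alpha = best$alpha,
                 best_lambda = best$lambda, best_deviance = best$deviance,
                 rule = "minimum LOO deviance; ties toward larger lambda, then larger alpha"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: alpha = %.3g, lambda = %.4g (LOO deviance %.3f)\n",
              x$best_alpha, x$best_lambda, x$best_deviance))
  cat("rule:", x$rule, "\n")
  invisible(x)
}

#' Sandwich standard errors on the active set
#'
#' Attaches Wald inference to the nonzero coefficients of a penalized fit via
#' the sandwich covariance `(H + L)^-1 H (H + L)^-1` restricted to the active
#' columns (plus the unpenalized intercept and age), where H is the observed
#' negative log-likelihood Hessian at the fit and L is diagonal with
#' `lambda (1 - alpha) + lambda alpha / |beta_j|` for penalized active
#' coefficients (local quadratic curvature of the l1 term) and 0 for the
#' intercept and age.  At lambda = 0 this reduces to the inverse
#' observed-information covariance of plain logistic regression.  Standard
#' errors are reported on the original (unstandardized) coefficient scale.
#'
#' @param fit A converged `interaction_fit` with non-empty active set.
#' @param design The `interaction_design` it was fitted on.
#' @param y Outcome (default the design's own).
#' @return The fit augmented with `inference` (data frame: term, estimate,
#'   se, z, p), and vectors `se` and `p_value` named by term.
#' @export
sandwich_se <- function(fit, design, y = design$y) {
  stopifnot(inherits(fit, "interaction_fit"), inherits(design, "interaction_design"))
  if (!fit$converged) stop("fit did not converge; refusing to compute standard errors")
  if (length(fit$active_set) == 0L) stop("active set is empty; nothing to test")
  cols <- c("(Intercept)", fit$active_set, if (design$include_age) "age")
  Xa <- design$X[, cols, drop = FALSE]
  eta <- drop(design$X %*% fit$beta_std)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  H <- crossprod(Xa, Xa * w)
  lam_diag <- vapply(cols, function(cn) {
    if (cn %in% fit$active_set) {
      fit$lambda * (1 - fit$alpha) + fit$lambda * fit$alpha / abs(fit$beta_std[[cn]])
    } else {
      0
    }
  }, numeric(1))
  M <- H + diag(lam_diag, nrow = length(cols))
  Minv <- tryCatch(solve(M), error = function(e) {
    stop("(H + Lambda) is singular; increase lambda or reduce the active set")
  })
  cov_std <- Minv %*% H %*% Minv

  # transform covariance to the original coefficient scale
  k <- length(cols)
  Tm <- diag(1, k)
  dimnames(Tm) <- list(cols, cols)
  for (cn in fit$active_set) {
    s <- design$scale[[cn]]
    Tm[cn, cn] <- 1 / s
    Tm["(Intercept)", cn] <- -design$center[[cn]] / s
  }
  cov_orig <- Tm %*% cov_std %*% t(Tm)
  se <- sqrt(pmax(diag(cov_orig), 0))

  est <- vapply(cols, function(cn) {
    if (cn == "(Intercept)") fit$beta0
    else if (cn == "age") fit$beta_age
    else c(fit$beta_main, fit$beta_pair)[[cn]]
  }, numeric(1))
  z <- est / se
  pval <- 2 * pnorm(-abs(z))
  fit$inference <- data.frame(term = cols, estimate = est, se = se, z = z,
                              p = pval, row.names = NULL)
  fit$se <- setNames(se, cols)
  fit$p_value <- setNames(pval, cols)
  fit$cov <- cov_orig
  fit
}

#' Odds ratio for a log-odds coefficient
#'
#' `exp(coefficient)`: the multiplicative change in the odds of case
#' membership for a one-unit increase in the corresponding column (for an
#' interaction column, a onefold increase in the product of the two
#' expression levels), all else held fixed.
#'
#' @param coefficient Finite regression coefficient(s).
#' @return `exp(coefficient)`.
#' @export
#' @examples
#' odds_ratio(0.21)   # 1.23
#' odds_ratio(-0.62)  # 0.54
odds_ratio <- function(coefficient) {
  if (any(!is.finite(coefficient))) stop("coefficient must be finite")
  exp(coefficient)
}

#' Symmetric coefficient table with significance marks
#'
#' Arranges a fit as a genes x genes table: main effects on the diagonal,
#' pairwise interaction coefficients in the upper triangle, zeros for
#' inactive entries.  Active entries with sandwich p-values are marked
#' `"*"` (p < 0.05) or `"**"` (p < 0.0005).  Raw p-values are used by
#' default, mirroring the original reporting; `adjust = "BH"` applies a
#' Benjamini-Hochberg correction across the active set first.
#'
#' @param fit An `interaction_fit`, ideally after [sandwich_se()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @param star_p,double_star_p Mark thresholds.
#' @return An `interaction_table`: `coefficients` matrix, `marks` matrix, and
#'   a `long` data frame (term, type, estimate, se, z, p, mark).
#' @export
report_table <- function(fit, adjust = c("none", "BH"),
                         star_p = 0.05, double_star_p = 0.0005) {
  stopifnot(inherits(fit, "interaction_fit"))
  adjust <- match.arg(adjust)
  genes <- fit$genes
  m <- length(genes)
  co <- matrix(0, m, m, dimnames = list(genes, genes))
  mk <- matrix("", m, m, dimnames = list(genes, genes))
  diag(co) <- fit$beta_main[genes]
  for (nm in names(fit$beta_pair)) {
    gs <- strsplit(nm, ":", fixed = TRUE)[[1]]
    co[gs[1], gs[2]] <- fit$beta_pair[[nm]]
  }
  pv <- fit$p_value
  if (!is.null(pv)) {
    active_terms <- intersect(names(pv), fit$active_set)
    padj <- pv[active_terms]
    if (adjust == "BH") padj <- stats::p.adjust(padj, method = "BH")
    mark_of <- function(p) if (p < double_star_p) "**" else if (p < star_p) "*" else ""
    for (nm in active_terms) {
      mark <- mark_of(padj[[nm]])
      if (!nzchar(mark)) next
      if (nm %in% genes) {
        mk[nm, nm] <- mark
      } else {
        gs <- strsplit(nm, ":", fixed = TRUE)[[1]]
        mk[gs[1], gs[2]] <- mark
      }
    }
  }
  long <- data.frame(
    term = c(names(fit$beta_main), names(fit$beta_pair)),
    type = c(rep("main", length(fit$beta_main)), rep("pair", length(fit$beta_pair))),
    estimate = c(fit$beta_main, fit$beta_pair), row.names = NULL)
  if (!is.null(fit$inference)) {
    inf <- fit$inference
    long$se <- inf$se[match(long$term, inf$term)]
    long$z <- inf$z[match(long$term, inf$term)]
    long$p <- inf$p[match(long$term, inf$term)]
  }
  long$mark <- vapply(long$term, function(nm) {
    if (nm %in% genes) mk[nm, nm]
    else {
      gs <- strsplit(nm, ":", fixed = TRUE)[[1]]
      mk[gs[1], gs[2]]
    }
  }, character(1))
  structure(list(coefficients = co, marks = mk, long = long,
                 adjust = adjust),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  shown <- matrix(paste0(signif(x$coefficients, 2), x$marks),
                  nrow = nrow(x$coefficients),
                  dimnames = dimnames(x$coefficients))
  shown[x$coefficients == 0 & x$marks == ""] <- "."
  shown[lower.tri(shown)] <- ""
  print(as.data.frame(shown), right = TRUE)
  cat("* p <", 0.05, "  ** p <", 5e-04,
      if (x$adjust == "BH") " (BH-adjusted)" else " (raw p-values)", "\n")
  invisible(x)
}

#' Write an interaction table to disk
#'
#' @param table An `interaction_table`.
#' @param prefix Output path prefix; writes `<prefix>_matrix.tsv` and
#'   `<prefix>_long.tsv`.
#' @return Invisibly, the files written.
#' @export
write_interaction_table <- function(table, prefix) {
  stopifnot(inherits(table, "interaction_table"))
  f1 <- paste0(prefix, "_matrix.tsv")
  f2 <- paste0(prefix, "_long.tsv")
  utils::write.table(table$coefficients, f1, sep = "\t", quote = FALSE)
  utils::write.table(table$long, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' End-to-end cross-group interaction analysis
#'
#' Convenience wrapper: expands the design, selects (alpha, lambda) by LOOCV,
#' refits on all samples, attaches sandwich inference when the active set is
#' non-empty, and computes Hosmer-Lemeshow and ROC diagnostics.
#'
#' @param data An `expression_dataset`.
#' @param case_group,control_group Group labels for Y = 1 / Y = 0.
#' @param alpha_grid,n_lambda,lambda_min_ratio LOOCV grid, see
#'   [loocv_select()].
#' @param include_age Include the unpenalized age column.
#' @param hl_groups Hosmer-Lemeshow bin count.
#' @return List with `design`, `cv`, `fit`, `table`, `diagnostics`.
#' @export
interaction_analysis <- function(data, case_group, control_group,
                                 alpha_grid = seq(0.1, 1, by = 0.1),
                                 n_lambda = 50, lambda_min_ratio = 1e-4,
                                 include_age = TRUE, hl_groups = 10) {
  design <- expand_design(data, case_group, control_group, include_age = include_age)
  cv <- loocv_select(design, alpha_grid = alpha_grid, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  fit <- fit_elastic_net(design, cv$best_alpha, cv$best_lambda)
  if (length(fit$active_set) > 0L && fit$converged) {
    fit <- sandwich_se(fit, design)
  }
  probs <- predict(fit, design)
  diag <- model_diagnostics(probs, design$y, g = hl_groups)
  list(design = design, cv = cv, fit = fit,
       table = report_table(fit), diagnostics = diag)
}
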