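# Independent oracles and fixture builders used across the suite.

# Global maximizer of the penalized binomial likelihood by exhaustive
# enumeration of sign patterns of the penalized coefficients: within each
# pattern the objective is smooth (|b| = s*b), maximized with gradient BFGS;
# the best *true* objective over all patterns is the global optimum for
# small p.  Completely independent of the coordinate-descent solver.
enet_oracle <- function(X, y, penalty, alpha, lambda) {
  p <- ncol(X)
  pen_idx <- which(penalty > 0)
  free_idx <- which(penalty == 0)
  true_obj <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - ifelse(eta > 35, eta, log1p(exp(eta))))
    ll - lambda * (1 - alpha) / 2 * sum(beta[pen_idx]^2) -
      lambda * alpha * sum(abs(beta[pen_idx]))
  }
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), length(pen_idx))))
  best <- -Inf
  best_beta <- numeric(p)
  for (k in seq_len(nrow(patterns))) {
    s <- patterns[k, ]
    act <- pen_idx[s != 0]
    par_idx <- c(free_idx, act)
    if (length(par_idx) == 0L) {
      cand <- numeric(p)
      ob <- true_obj(cand)
      if (ob > best) { best <- ob; best_beta <- cand }
      next
    }
    sgn <- numeric(p)
    sgn[pen_idx] <- s
    negfn <- function(par) {
      beta <- numeric(p)
      beta[par_idx] <- par
      eta <- drop(X %*% beta)
      ll <- sum(y * eta - ifelse(eta > 35, eta, log1p(exp(eta))))
      -(ll - lambda * (1 - alpha) / 2 * sum(beta[act]^2) -
          lambda * alpha * sum(sgn[act] * beta[act]))
    }
    neggr <- function(par) {
      beta <- numeric(p)
      beta[par_idx] <- par
      pr <- plogis(drop(X %*% beta))
      g <- drop(crossprod(X, y - pr))
      g[act] <- g[act] - lambda * (1 - alpha) * beta[act] - lambda * alpha * sgn[act]
      -g[par_idx]
    }
    opt <- optim(numeric(length(par_idx)), negfn, neggr, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-16))
    beta <- numeric(p)
    beta[par_idx] <- opt$par
    ob <- true_obj(beta)
    if (ob > best) { best <- ob; best_beta <- beta }
  }
  list(objective = best, beta = best_beta)
}

# Naive agglomerative clustering oracle: clusters tracked as index sets,
# inter-cluster distance recomputed from the original matrix at every step
# (average / single / complete), ties broken toward the lexicographically
# smallest pair of cluster labels.  Returns merge heights and the partition
# after each merge (canonical strings).
brute_agglomerate <- function(d, linkage = "average") {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  partitions <- list()
  linkfun <- switch(linkage, average = mean, single = min, complete = max)
  canon <- function(cl) {
    paste(sort(vapply(cl, function(ix) paste(sort(labels[ix]), collapse = ","),
                      character(1))), collapse = " | ")
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    bestkey <- ""
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dv <- linkfun(d[clusters[[a]], clusters[[b]], drop = FALSE])
        key <- paste(min(labels[clusters[[a]]][1], labels[clusters[[b]]][1]),
                     max(labels[clusters[[a]]][1], labels[clusters[[b]]][1]))
        if (dv < bestd - 1e-12 || (abs(dv - bestd) <= 1e-12 && key < bestkey)) {
          bestd <- dv
          best <- c(a, b)
          bestkey <- key
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, bestd)
    partitions[[length(partitions) + 1L]] <- canon(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(membership) {
  paste(sort(vapply(split(names(membership), membership),
                    function(g) paste(sort(g), collapse = ","), character(1))),
        collapse = " | ")
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# Small three-gene cohort whose case labels come from a single planted
# product-term logistic effect (centered so classes are roughly balanced).
make_toy_interaction <- function(n, beta_pair = 1.2, seed = 1, null = FALSE) {
  set.seed(seed)
  X <- matrix(exp(rnorm(n * 3)), n, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  y <- if (null) {
    rbinom(n, 1, 0.5)
  } else {
    rbinom(n, 1, plogis(beta_pair * (X[, 1] * X[, 2] - exp(1))))
  }
  expression_dataset(X, ifelse(y == 1, "case", "ctrl"), age = rep(30, n))
}

# Random small logistic instance for solver oracle tests.
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(20:50, 1)
  p_pen <- sample(1:4, 1)
  X <- cbind(1, matrix(rnorm(n * p_pen), n, p_pen))
  beta_true <- c(runif(1, -0.5, 0.5), runif(p_pen, -1, 1))
  y <- rbinom(n, 1, plogis(drop(X %*% beta_true)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y, penalty = c(0, rep(1, p_pen)),
       alpha = runif(1, 0.1, 1), lambda = runif(1, 0.1, 3))
}
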