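test_that("design expansion builds the interaction columns and outcome correctly", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  des <- expand_design(d, "LT", "HT")
  expect_equal(ncol(des$X), 1 + 13 + 78 + 1)
  expect_equal(length(des$pair_names), choose(13, 2))
  expect_equal(sum(des$y), 59)
  expect_equal(sum(1 - des$y), 69)
  # penalized columns standardized to mean 0, variance 1
  pen_cols <- c(des$main_names, des$pair_names)
  expect_true(all(abs(colMeans(des$X[, pen_cols])) < 1e-12))
  expect_true(all(abs(apply(des$X[, pen_cols], 2, var) - 1) < 1e-12))
  # interaction columns are products of the raw gene columns
  v <- d$values[d$group %in% c("LT", "HT"), ]
  expect_equal(unname(des$X_raw[, "CD3G:CD20"]),
               unname(v[, "CD3G"] * v[, "CD20"]))

  # toy gene count
  toy <- make_toy_interaction(30, seed = 1)
  des3 <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  expect_equal(length(des3$pair_names), 3)
  expect_equal(ncol(des3$X), 1 + 3 + 3)

  expect_error(expand_design(d, "XX", "HT"), "XX")
  dconst <- expression_dataset(cbind(gA = rep(2, 20), gB = exp(rnorm(20))),
                               rep(c("case", "ctrl"), 10), age = rep(30, 20))
  expect_error(expand_design(dconst, "case", "ctrl"), "gA")
})

test_that("penalized log-likelihood matches independent recomputation", {
  toy <- make_toy_interaction(40, seed = 2)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  p <- ncol(des$X)
  # all-zero coefficients: plain log-likelihood n log(1/2), no penalty
  expect_equal(penalized_loglik(numeric(p), des, alpha = 0.5, lambda = 3),
               length(des$y) * log(0.5))
  # random coefficients: term-by-term recomputation
  set.seed(3)
  for (k in 1:5) {
    beta <- rnorm(p, sd = 0.3)
    alpha <- runif(1, 0.1, 1)
    lambda <- runif(1, 0, 2)
    eta <- drop(des$X %*% beta)
    ll <- sum(dbinom(des$y, 1, plogis(eta), log = TRUE))
    pen_idx <- which(des$penalty > 0)
    expected <- ll - lambda * (1 - alpha) / 2 * sum(beta[pen_idx]^2) -
      lambda * alpha * sum(abs(beta[pen_idx]))
    expect_equal(penalized_loglik(beta, des, alpha = alpha, lambda = lambda),
                 expected, tolerance = 1e-10)
    # lambda = 0 reduces to the plain log-likelihood
    expect_equal(penalized_loglik(beta, des, alpha = alpha, lambda = 0), ll,
                 tolerance = 1e-10)
  }
  expect_error(penalized_loglik(numeric(p), des, alpha = 0, lambda = 1), "alpha")
  expect_error(penalized_loglik(numeric(p), des, alpha = 0.5, lambda = -1),
               "lambda")
})

test_that("above lambda_max the fit is the null model with closed-form intercept", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  des <- expand_design(d, "LT", "HT", include_age = FALSE)
  for (alpha in c(0.3, 1)) {
    lm_a <- lambda_max(des, alpha)
    for (lam in c(lm_a, 2 * lm_a)) {
      f <- fit_elastic_net(des, alpha, lam)
      expect_length(f$active_set, 0)
      expect_true(all(c(f$beta_main, f$beta_pair) == 0))
      expect_equal(f$beta0, log(sum(des$y) / sum(1 - des$y)), tolerance = 1e-6)
    }
    # slightly below lambda_max at least one coefficient activates
    f2 <- fit_elastic_net(des, alpha, lm_a * 0.95)
    expect_gt(length(f2$active_set), 0)
  }
})

test_that("the vanishing-penalty limit agrees with the plain logistic MLE", {
  set.seed(2)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(-0.3 + X %*% c(0.8, -0.5, 0.3)))
  Xd <- cbind(1, X)
  r <- enet_logistic(Xd, y, c(0, 1, 1, 1), alpha = 0.5, lambda = 1e-8,
                     tol = 1e-10)
  g <- glm.fit(Xd, y, family = binomial())
  expect_lt(max(abs(r$beta - g$coefficients)), 1e-3)
})

test_that("coordinate descent matches the sign-enumeration oracle on small instances", {
  for (seed in 1:6) {
    inst <- random_instance(seed)
    r <- enet_logistic(inst$X, inst$y, inst$penalty, inst$alpha, inst$lambda,
                       tol = 1e-10, max_iter = 1e5)
    oracle <- enet_oracle(inst$X, inst$y, inst$penalty, inst$alpha, inst$lambda)
    expect_equal(r$objective, oracle$objective, tolerance = 1e-6)
  }
})

test_that("solver agrees with glmnet on a matched objective", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  n <- 150
  X <- scale(matrix(rnorm(n * 5), n, 5))
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0, 0, 0.3)))
  for (alpha in c(0.3, 1)) {
    lam_g <- 0.05
    r <- enet_logistic(cbind(1, X), y, c(0, rep(1, 5)), alpha,
                       lambda = lam_g * n, tol = 1e-10, max_iter = 1e5)
    gn <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                         lambda = lam_g, standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(r$beta - as.numeric(coef(gn)))), 1e-4)
  }
})

test_that("objective is non-decreasing across outer iterations", {
  for (seed in 7:10) {
    inst <- random_instance(seed)
    r <- enet_logistic(inst$X, inst$y, inst$penalty, inst$alpha, inst$lambda)
    expect_true(all(diff(r$objective_path) >= -1e-9))
  }
})

test_that("original-scale solution is invariant to positive gene rescaling", {
  toy <- make_toy_interaction(120, seed = 4)
  des1 <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  f1 <- fit_elastic_net(des1, alpha = 0.5, lambda = 2, tol = 1e-9)

  v2 <- toy$values
  v2[, "g1"] <- v2[, "g1"] * 3.7
  toy2 <- expression_dataset(v2, toy$group, toy$age, toy$sample_id)
  des2 <- expand_design(toy2, "case", "ctrl", include_age = FALSE)
  f2 <- fit_elastic_net(des2, alpha = 0.5, lambda = 2, tol = 1e-9)

  # standardized problem identical, so original-scale coefficients rescale
  expect_equal(f2$beta_main[["g1"]] * 3.7, f1$beta_main[["g1"]], tolerance = 1e-6)
  expect_equal(f2$beta_main[["g2"]], f1$beta_main[["g2"]], tolerance = 1e-6)
  expect_equal(f2$beta_pair[["g1:g2"]] * 3.7, f1$beta_pair[["g1:g2"]],
               tolerance = 1e-6)
  expect_equal(f2$beta0, f1$beta0, tolerance = 1e-6)
})

test_that("single-class outcomes and invalid hyperparameters are rejected", {
  toy <- make_toy_interaction(30, seed = 5)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  expect_error(enet_logistic(des$X, rep(1, nrow(des$X)), des$penalty, 0.5, 1),
               "single class")
  expect_error(fit_elastic_net(des, alpha = 1.5, lambda = 1), "alpha")
  expect_error(fit_elastic_net(des, alpha = 0.5, lambda = -1), "lambda")
})

test_that("LOOCV selects the only available grid point and records the rule", {
  toy <- make_toy_interaction(40, seed = 6)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  cv <- loocv_select(des, alpha_grid = 0.5, lambda_path = 0.8)
  expect_equal(cv$best_alpha, 0.5)
  expect_equal(cv$best_lambda, 0.8)
  expect_equal(nrow(cv$grid), 1)
  expect_equal(cv$best_deviance, min(cv$grid$deviance[cv$grid$valid]))
  expect_match(cv$rule, "larger lambda")
})

test_that("LOOCV retains a strongly planted interaction", {
  hits <- 0
  for (s in 1:10) {
    toy <- make_toy_interaction(300, beta_pair = 1.2, seed = 100 + s)
    des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
    cv <- loocv_select(des, alpha_grid = c(0.5, 1), n_lambda = 12,
                       lambda_min_ratio = 1e-3)
    f <- fit_elastic_net(des, cv$best_alpha, cv$best_lambda)
    if ("g1:g2" %in% f$active_set) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("sandwich covariance reduces to the observed information at lambda = 0", {
  set.seed(9)
  toy <- make_toy_interaction(250, seed = 9)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  f <- fit_elastic_net(des, alpha = 0.5, lambda = 0, tol = 1e-10)
  f <- sandwich_se(f, des)
  v <- toy$values[, ]
  df <- data.frame(y = des$y, g1 = v[, 1], g2 = v[, 2], g3 = v[, 3],
                   g12 = v[, 1] * v[, 2], g13 = v[, 1] * v[, 3],
                   g23 = v[, 2] * v[, 3])
  g <- suppressWarnings(
    glm(y ~ g1 + g2 + g3 + g12 + g13 + g23, data = df, family = binomial()))
  se_glm <- sqrt(diag(vcov(g)))
  expect_equal(unname(f$se[c("g1", "g2", "g3", "g1:g2", "g1:g3", "g2:g3")]),
               unname(se_glm[c("g1", "g2", "g3", "g12", "g13", "g23")]),
               tolerance = 1e-3)
  expect_equal(f$se[["(Intercept)"]], se_glm[["(Intercept)"]], tolerance = 1e-3)
})

test_that("increasing the penalty weakly shrinks every sandwich standard error", {
  toy <- make_toy_interaction(200, seed = 10)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  f <- fit_elastic_net(des, alpha = 0.2, lambda = 1, tol = 1e-9)
  f1 <- sandwich_se(f, des)
  f2 <- f
  f2$lambda <- 2
  f2 <- sandwich_se(f2, des)
  expect_true(all(f2$se <= f1$se + 1e-12))
})

test_that("ridge-dominated sandwich errors are close to bootstrap errors", {
  set.seed(12)
  n <- 500
  toy <- make_toy_interaction(n, beta_pair = 0.8, seed = 12)
  des <- expand_design(toy, "case", "ctrl", include_age = FALSE)
  lam <- 5
  f <- fit_elastic_net(des, alpha = 0.01, lambda = lam, tol = 1e-8)
  f <- sandwich_se(f, des)
  terms <- intersect(c("g1:g2"), f$active_set)
  expect_gt(length(terms), 0)
  boot <- replicate(200, {
    idx <- sample(n, replace = TRUE)
    v <- toy$values[idx, ]
    db <- expression_dataset(v, toy$group[idx], toy$age[idx])
    desb <- expand_design(db, "case", "ctrl", include_age = FALSE)
    fb <- fit_elastic_net(desb, alpha = 0.01, lambda = lam, tol = 1e-6)
    c(fb$beta_main, fb$beta_pair)[terms]
  })
  boot_se <- sd(boot)
  expect_lt(abs(f$se[[terms]] - boot_se) / boot_se, 0.25)
})

test_that("odds ratios exponentiate coefficients", {
  expect_equal(round(odds_ratio(0.21), 2), 1.23)
  expect_equal(odds_ratio(0), 1.0)
  expect_equal(round(odds_ratio(-0.62), 2), 0.54)
  expect_error(odds_ratio(Inf), "finite")
})

test_that("report tables mirror the fit with correct marks", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  des <- expand_design(d, "LT", "HT")
  # empty active set: all-zero table, no marks
  f0 <- fit_elastic_net(des, 1, 2 * lambda_max(des, 1))
  tab0 <- report_table(f0)
  expect_true(all(tab0$coefficients == 0))
  expect_true(all(tab0$marks == ""))

  # synthetic p-values exercise the mark thresholds
  f <- fit_elastic_net(des, 0.5, 3)
  expect_gt(length(f$active_set), 0)
  f$p_value <- setNames(rep(0.5, length(f$active_set)), f$active_set)
  f$p_value[f$active_set[1]] <- 0.01
  f$p_value[f$active_set[2]] <- 1e-5
  tab <- report_table(f)
  expect_equal(sum(tab$marks == "*"), 1)
  expect_equal(sum(tab$marks == "**"), 1)
  # diagonal holds mains, upper triangle pairs, lower triangle zero
  expect_true(all(tab$coefficients[lower.tri(tab$coefficients)] == 0))
})
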