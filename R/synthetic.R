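#' Construct an expression dataset
#'
#' The core data container: a samples x genes matrix of non-negative relative
#' expression values (qRT-PCR style, arbitrary units) with one group label and
#' an age per sample.
#'
#' @param values Numeric matrix, samples x genes, non-negative, no missing
#'   values; column names are gene names.
#' @param group Character vector of group labels, one per sample
#'   (e.g. HT/AT/NO/LT).
#' @param age Numeric vector of ages in years, one per sample.
#' @param sample_id Optional sample identifiers (default S1, S2, ...).
#' @return An object of class `expression_dataset` with elements `values`,
#'   `genes`, `sample_id`, `group`, `age`.
#' @export
expression_dataset <- function(values, group, age, sample_id = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have gene column names")
  genes <- colnames(values)
  if (anyDuplicated(genes)) stop("duplicate gene names: ",
                                 paste(unique(genes[duplicated(genes)]), collapse = ", "))
  n <- nrow(values)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id: ",
                                     paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  group <- as.character(group)
  age <- as.numeric(age)
  if (length(group) != n || length(age) != n || length(sample_id) != n) {
    stop("group, age and sample_id must each have one entry per sample")
  }
  if (anyNA(values) || any(!is.finite(values))) stop("values contain missing or non-finite entries")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyNA(age)) stop("age contains missing values")
  rownames(values) <- sample_id
  structure(list(values = values, genes = genes, sample_id = sample_id,
                 group = group, age = age),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "samples x", length(x$genes), "genes\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Drop samples from a dataset
#'
#' @param data An `expression_dataset`.
#' @param sample_ids Ids to remove (e.g. outliers flagged by [flag_outliers()]).
#' @return The dataset without the named samples.
#' @export
drop_samples <- function(data, sample_ids) {
  stopifnot(inherits(data, "expression_dataset"))
  keep <- !(data$sample_id %in% sample_ids)
  out <- expression_dataset(data$values[keep, , drop = FALSE],
                            data$group[keep], data$age[keep],
                            data$sample_id[keep])
  attributes(out)$metadata <- attr(data, "metadata")
  out
}

#' Synthetic cohort configuration
#'
#' Full recipe for [generate_dataset()]: per-group sample counts matching the
#' study design (HT 69, AT 19, NO 33, LT 59), block-structured log-scale
#' correlations, an overall correlation tightening factor and a downward
#' log-mean shift applied to the long-term (LT) group, per-group age
#' distributions, and an optional planted logistic coefficient set used when
#' case labels are drawn from the interaction model itself.
#'
#' @param group_sizes Named integer vector of samples per group.
#' @param blocks List of [gene_block()] specs; genes must be disjoint.
#' @param cross_rho Baseline correlation between genes of different blocks.
#' @param tighten_factor Multiplier >= 1 applied to all LT off-diagonal
#'   correlations (clipped at |r| = 0.99, then projected back to the nearest
#'   positive-definite correlation matrix if needed).
#' @param lt_mean_shift Shift (<= 0) added to LT log-means (reduced expression
#'   in long-term disease); either a scalar or a named per-gene vector.
#' @param age_mean,age_sd Named per-group age means/SDs in years; ages are
#'   truncated at 0.
#' @param label_mode `"group_first"` (groups fixed by design, expression drawn
#'   per group) or `"label_from_model"` (expression drawn from the baseline
#'   structure, case labels drawn Bernoulli from the interaction logistic
#'   model with `planted_beta`).
#' @param planted_beta Optional list with components `intercept` (optional),
#'   `main` (named vector), `pair` (named vector, names `"A:B"`), `age`
#'   (scalar).  Required in `label_from_model` mode.
#' @param case_label,control_label Group labels assigned to Y=1 / Y=0 samples
#'   in `label_from_model` mode.
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(group_sizes = c(HT = 69, AT = 19, NO = 33, LT = 59),
                             blocks = default_gene_blocks(),
                             cross_rho = 0.3,
                             tighten_factor = 1.15,
                             lt_mean_shift = -0.3,
                             age_mean = c(HT = 28, AT = 16, NO = 13, LT = 32),
                             age_sd = c(HT = 10, AT = 8, NO = 6, LT = 12),
                             label_mode = c("group_first", "label_from_model"),
                             planted_beta = NULL,
                             case_label = "LT", control_label = "HT",
                             seed = 1L) {
  label_mode <- match.arg(label_mode)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes < 0)) stop("group counts must be >= 0")
  genes <- unlist(lapply(blocks, `[[`, "genes"))
  if (anyDuplicated(genes)) {
    stop("genes must be disjoint across blocks; duplicated: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (abs(cross_rho) >= 1) stop("|cross_rho| must be < 1")
  if (tighten_factor < 1) stop("tighten_factor must be >= 1")
  if (any(lt_mean_shift > 0)) stop("lt_mean_shift must be <= 0")
  if (length(lt_mean_shift) > 1L && !all(names(lt_mean_shift) %in% genes)) {
    stop("per-gene lt_mean_shift names must match configured genes")
  }
  if (label_mode == "label_from_model" && is.null(planted_beta)) {
    stop("label_from_model mode requires planted_beta")
  }
  cfg <- structure(list(group_sizes = group_sizes, blocks = blocks,
                        cross_rho = cross_rho, tighten_factor = tighten_factor,
                        lt_mean_shift = lt_mean_shift,
                        age_mean = age_mean, age_sd = age_sd,
                        label_mode = label_mode, planted_beta = planted_beta,
                        case_label = case_label, control_label = control_label,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  # fail fast if the assembled baseline matrix is not positive definite
  invisible(baseline_correlation(cfg))
  cfg
}

config_genes <- function(config) unlist(lapply(config$blocks, `[[`, "genes"), use.names = FALSE)

config_mean_log <- function(config) {
  unlist(lapply(config$blocks, `[[`, "mean_log_expr"))[config_genes(config)]
}

config_sd_log <- function(config) {
  unlist(lapply(config$blocks, `[[`, "sd_log_expr"))[config_genes(config)]
}

# per-gene LT shift vector, expanding a scalar lt_mean_shift
config_lt_shift <- function(config) {
  genes <- config_genes(config)
  sh <- setNames(rep(0, length(genes)), genes)
  if (length(config$lt_mean_shift) == 1L && is.null(names(config$lt_mean_shift))) {
    sh[] <- config$lt_mean_shift
  } else {
    sh[names(config$lt_mean_shift)] <- config$lt_mean_shift
  }
  sh
}

#' Baseline log-scale correlation matrix implied by a configuration
#'
#' Within-block entries take each block's `within_rho`; between-block entries
#' take `cross_rho`.
#'
#' @param config A `synthetic_config`.
#' @return Correlation matrix over the configured genes.
#' @export
baseline_correlation <- function(config) {
  genes <- config_genes(config)
  m <- length(genes)
  R <- matrix(config$cross_rho, m, m, dimnames = list(genes, genes))
  for (b in config$blocks) {
    R[b$genes, b$genes] <- b$within_rho
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("baseline correlation matrix is not positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 3),
         "); reduce cross_rho or block within_rho values")
  }
  R
}

#' Long-term-group correlation matrix: tightened and repaired
#'
#' Off-diagonal correlations are multiplied by `tighten_factor`, clipped at
#' |r| = 0.99, and, if the result is no longer positive definite, projected to
#' the nearest positive-definite correlation matrix ([Matrix::nearPD()]).
#'
#' @param config A `synthetic_config`.
#' @return Correlation matrix for the LT group.
#' @export
lt_correlation <- function(config) {
  R <- baseline_correlation(config)
  Rt <- R * config$tighten_factor
  Rt[Rt > 0.99] <- 0.99
  Rt[Rt < -0.99] <- -0.99
  diag(Rt) <- 1
  ev <- eigen(Rt, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    Rt <- as.matrix(Matrix::nearPD(Rt, corr = TRUE, eig.tol = 1e-7)$mat)
    dimnames(Rt) <- dimnames(R)
    ev <- eigen(Rt, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("tightened LT correlation matrix could not be repaired to positive ",
           "definite (tighten_factor = ", config$tighten_factor, ")")
    }
  }
  Rt
}

draw_group_values <- function(n, mu, sdlog, R) {
  Sigma <- diag(sdlog) %*% R %*% diag(sdlog)
  z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  if (n == 1L) z <- matrix(z, nrow = 1)
  colnames(z) <- names(mu)
  exp(z)
}

draw_ages <- function(n, mean, sd) {
  a <- rnorm(n, mean, sd)
  while (any(a < 0)) a[a < 0] <- rnorm(sum(a < 0), mean, sd)
  a
}

# expected value of exp(z_i) and exp(z_i + z_j) under the log-scale model;
# used to center the planted intercept deterministically
lognormal_moments <- function(config) {
  mu <- config_mean_log(config)
  s <- config_sd_log(config)
  R <- baseline_correlation(config)
  genes <- names(mu)
  EX <- exp(mu + s^2 / 2)
  EXX <- outer(genes, genes, Vectorize(function(a, b) {
    exp(mu[a] + mu[b] + (s[a]^2 + s[b]^2) / 2 + s[a] * s[b] * R[a, b])
  }))
  dimnames(EXX) <- list(genes, genes)
  list(EX = EX, EXX = EXX)
}

normalize_pair_names <- function(pair, genes) {
  if (length(pair) == 0) return(setNames(numeric(0), character(0)))
  nm <- strsplit(names(pair), ":", fixed = TRUE)
  bad <- vapply(nm, function(p) length(p) != 2 || !all(p %in% genes), logical(1))
  if (any(bad)) stop("unknown genes in planted pair names: ",
                     paste(names(pair)[bad], collapse = ", "))
  ord <- vapply(nm, function(p) paste(p[order(match(p, genes))], collapse = ":"),
                character(1))
  setNames(as.numeric(pair), ord)
}

planted_linear_predictor <- function(values, age, config) {
  pb <- config$planted_beta
  genes <- config_genes(config)
  main <- setNames(numeric(length(genes)), genes)
  if (!is.null(pb$main)) main[names(pb$main)] <- pb$main
  pair <- normalize_pair_names(pb$pair, genes)
  eta <- drop(values %*% main)
  for (nm in names(pair)) {
    gs <- strsplit(nm, ":", fixed = TRUE)[[1]]
    eta <- eta + pair[nm] * values[, gs[1]] * values[, gs[2]]
  }
  beta_age <- if (is.null(pb$age)) 0 else pb$age
  eta <- eta + beta_age * age
  b0 <- if (!is.null(pb$intercept)) {
    pb$intercept
  } else {
    # center so that the expected linear predictor is 0 (balanced classes)
    mom <- lognormal_moments(config)
    e <- sum(main * mom$EX)
    for (nm in names(pair)) {
      gs <- strsplit(nm, ":", fixed = TRUE)[[1]]
      e <- e + pair[nm] * mom$EXX[gs[1], gs[2]]
    }
    grp <- config$control_label
    amean <- if (grp %in% names(config$age_mean)) config$age_mean[[grp]] else mean(config$age_mean)
    -(e + beta_age * amean)
  }
  b0 + eta
}

#' Generate a synthetic expression cohort
#'
#' Samples log-expression from a multivariate normal with the configured block
#' correlation structure and exponentiates, per group.  The LT group uses the
#' tightened correlation matrix and shifted log-means.  In
#' `label_from_model` mode all samples are drawn from the baseline structure
#' and case labels are Bernoulli draws from the planted interaction logistic
#' model.
#'
#' @param config A [synthetic_config()].
#' @return An [expression_dataset()]; the configuration, seed and planted
#'   truth are stored in `attr(, "metadata")`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- config_genes(config)
  mu <- config_mean_log(config)
  s <- config_sd_log(config)
  R0 <- baseline_correlation(config)

  if (config$label_mode == "group_first") {
    vals <- list()
    grp <- list()
    ages <- list()
    for (g in names(config$group_sizes)) {
      n <- config$group_sizes[[g]]
      if (n == 0L) next
      R <- if (g == config$case_label) lt_correlation(config) else R0
      mug <- if (g == config$case_label) mu + config_lt_shift(config) else mu
      vals[[g]] <- draw_group_values(n, mug, s, R)
      grp[[g]] <- rep(g, n)
      am <- if (g %in% names(config$age_mean)) config$age_mean[[g]] else mean(config$age_mean)
      asd <- if (g %in% names(config$age_sd)) config$age_sd[[g]] else mean(config$age_sd)
      ages[[g]] <- draw_ages(n, am, asd)
    }
    values <- do.call(rbind, vals)
    group <- unlist(grp, use.names = FALSE)
    age <- unlist(ages, use.names = FALSE)
  } else {
    n <- sum(config$group_sizes)
    values <- draw_group_values(n, mu, s, R0)
    grp0 <- config$control_label
    am <- if (grp0 %in% names(config$age_mean)) config$age_mean[[grp0]] else mean(config$age_mean)
    asd <- if (grp0 %in% names(config$age_sd)) config$age_sd[[grp0]] else mean(config$age_sd)
    age <- draw_ages(n, am, asd)
    eta <- planted_linear_predictor(values, age, config)
    y <- rbinom(n, 1, plogis(eta))
    group <- ifelse(y == 1, config$case_label, config$control_label)
  }

  out <- expression_dataset(values, group, age)
  attr(out, "metadata") <- list(config = config, seed = config$seed,
                                truth = planted_truth(config))
  out
}

#' Exact generative parameters of a configuration
#'
#' Returns the parameters a dataset was (or would be) generated from, so
#' recovery tests can compare estimates against planted truth.  In
#' `group_first` mode the coefficient set is empty.
#'
#' @param config A [synthetic_config()].
#' @return List with `beta` (`main`, `pair`, `age`, and `intercept` when
#'   planted), `correlations` (per group), `mean_log` (per group), and the
#'   seed.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- config_genes(config)
  R0 <- baseline_correlation(config)
  Rlt <- lt_correlation(config)
  mu <- config_mean_log(config)
  corrs <- lapply(names(config$group_sizes), function(g) {
    if (g == config$case_label && config$label_mode == "group_first") Rlt else R0
  })
  names(corrs) <- names(config$group_sizes)
  means <- lapply(names(config$group_sizes), function(g) {
    if (g == config$case_label && config$label_mode == "group_first") {
      mu + config_lt_shift(config)
    } else {
      mu
    }
  })
  names(means) <- names(config$group_sizes)
  beta <- if (config$label_mode == "label_from_model") {
    pb <- config$planted_beta
    list(intercept = pb$intercept,
         main = if (is.null(pb$main)) setNames(numeric(0), character(0)) else pb$main,
         pair = normalize_pair_names(pb$pair, genes),
         age = if (is.null(pb$age)) 0 else pb$age)
  } else {
    list(main = setNames(numeric(0), character(0)),
         pair = setNames(numeric(0), character(0)),
         age = 0)
  }
  list(beta = beta, correlations = corrs, mean_log = means, seed = config$seed)
}
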