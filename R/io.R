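#' Read an expression table from delimited text
#'
#' Expects a header `sample_id, group, age` followed by one column per gene.
#' The delimiter is sniffed from the header line (tab when the line contains
#' more tabs than commas; comma otherwise).  Duplicate sample ids, duplicate
#' gene names, and non-numeric expression cells are rejected with informative
#' errors.
#'
#' @param path Path to a CSV/TSV file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("empty file: ", path)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "group", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  gene_cols <- setdiff(names(df), required)
  if (!length(gene_cols)) stop("no gene columns found")
  if (anyDuplicated(gene_cols)) {
    stop("duplicate gene names: ",
         paste(unique(gene_cols[duplicated(gene_cols)]), collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  vals <- as.matrix(df[gene_cols])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row ", bad[1], ", column '",
         gene_cols[bad[2]], "'")
  }
  colnames(vals) <- gene_cols
  expression_dataset(vals, df$group, df$age, df$sample_id)
}

#' Write an expression dataset as CSV with a JSON metadata sidecar
#'
#' @param data An `expression_dataset`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>_meta.json` (generator configuration and seed, when present).
#' @return Invisibly, the files written.
#' @export
write_expression <- function(data, prefix) {
  stopifnot(inherits(data, "expression_dataset"))
  f1 <- paste0(prefix, ".csv")
  df <- data.frame(sample_id = data$sample_id, group = data$group,
                   age = data$age, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$values, check.names = FALSE))
  utils::write.csv(df, f1, row.names = FALSE, quote = FALSE)
  files <- f1
  meta <- attr(data, "metadata")
  if (!is.null(meta)) {
    f2 <- paste0(prefix, "_meta.json")
    jsonlite::write_json(serialize_config(meta$config), f2,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f2)
  }
  invisible(files)
}

serialize_config <- function(config) {
  if (is.null(config)) return(NULL)
  list(group_sizes = as.list(config$group_sizes),
       blocks = lapply(config$blocks, function(b) {
         list(block_name = b$block_name, genes = b$genes,
              within_rho = b$within_rho,
              mean_log_expr = as.list(b$mean_log_expr),
              sd_log_expr = as.list(b$sd_log_expr))
       }),
       cross_rho = config$cross_rho,
       tighten_factor = config$tighten_factor,
       lt_mean_shift = config$lt_mean_shift,
       age_mean = as.list(config$age_mean),
       age_sd = as.list(config$age_sd),
       label_mode = config$label_mode,
       planted_beta = config$planted_beta,
       case_label = config$case_label,
       control_label = config$control_label,
       seed = config$seed)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' Validated flat configuration for [run_pipeline()].  Unknown keys are
#' rejected.
#'
#' @param input Path to an expression CSV/TSV, or an `expression_dataset`.
#' @param case_group,control_group Groups for the cross-group model.
#' @param strong_thr,moderate_thr Network edge thresholds.
#' @param min_n Minimum group size for network estimation.
#' @param z_max Outlier robust-z threshold.
#' @param exclude_outliers Drop flagged samples before analysis.
#' @param cluster_mode,linkage Clustering distance mode and linkage.
#' @param alpha_grid,n_lambda,lambda_min_ratio Model selection grid.
#' @param include_age Include age in the model.
#' @param ratio_num,ratio_den Genes of the ratio profile stage.
#' @param stages Subset of
#'   `c("outliers", "network", "cluster", "model", "diagnostics", "ratio")`
#'   to run.
#' @param out_prefix Output path prefix (directories created as needed).
#' @param seed Seed recorded into the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input,
                            case_group = "LT", control_group = "HT",
                            strong_thr = 0.9, moderate_thr = 0.8,
                            min_n = 20, z_max = 5, exclude_outliers = FALSE,
                            cluster_mode = "one_minus_r", linkage = "average",
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            n_lambda = 50, lambda_min_ratio = 1e-4,
                            include_age = TRUE,
                            ratio_num = "CTLA4", ratio_den = "CD3G",
                            stages = c("outliers", "network", "cluster",
                                       "model", "diagnostics", "ratio"),
                            out_prefix = NULL, seed = 1L) {
  if (!(moderate_thr > 0 && moderate_thr < strong_thr && strong_thr <= 1)) {
    stop("thresholds must satisfy 0 < moderate_thr < strong_thr <= 1")
  }
  if (min_n < 3) stop("min_n must be >= 3")
  if (z_max <= 0) stop("z_max must be > 0")
  if (identical(case_group, control_group)) {
    stop("case_group and control_group must differ")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  cluster_mode <- match.arg(cluster_mode, c("one_minus_r", "one_minus_abs_r"))
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  structure(list(input = input, case_group = case_group,
                 control_group = control_group, strong_thr = strong_thr,
                 moderate_thr = moderate_thr, min_n = min_n, z_max = z_max,
                 exclude_outliers = exclude_outliers,
                 cluster_mode = cluster_mode, linkage = linkage,
                 alpha_grid = alpha_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 include_age = include_age,
                 ratio_num = ratio_num, ratio_den = ratio_den,
                 stages = stages, out_prefix = out_prefix,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full relationship-profile pipeline
#'
#' Stages, each individually skippable: outlier screening, per-group
#' thresholded networks, per-group dendrograms, the cross-group elastic-net
#' interaction model with LOOCV and sandwich inference, model diagnostics,
#' and the ratio profile.  Every written output carries provenance metadata
#' (configuration hash, seed, package version); a stage error is re-raised
#' with the stage name, with earlier outputs preserved.
#'
#' @param config A [pipeline_config()].
#' @return A report list; written to `<out_prefix>_report.json` (plus
#'   per-stage files) when `out_prefix` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- if (inherits(config$input, "expression_dataset")) config$input
          else read_expression(config$input)
  prefix <- config$out_prefix
  if (!is.null(prefix)) {
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  }
  report <- list(provenance = list(
    config_hash = config_hash(config[setdiff(names(config),
                                             c("input", "out_prefix"))]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("t1dnet")),
    n_samples = length(data$sample_id)))
  warnings_seen <- character(0)
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  outliers <- run_stage("outliers", flag_outliers(data, z_max = config$z_max))
  if (!is.null(outliers)) {
    report$outliers <- list(flagged = outliers$flagged,
                            excluded = if (config$exclude_outliers) outliers$flagged else character(0))
    if (config$exclude_outliers && length(outliers$flagged)) {
      data <- drop_samples(data, outliers$flagged)
    }
  }

  networks <- run_stage("network", {
    nets <- lapply(unique(data$group), function(g) {
      build_network(data, g, strong_thr = config$strong_thr,
                    moderate_thr = config$moderate_thr, min_n = config$min_n)
    })
    names(nets) <- unique(data$group)
    nets
  })
  if (!is.null(networks)) {
    report$networks <- lapply(networks, function(nt) {
      if (isTRUE(nt$skipped)) {
        list(skipped = TRUE, reason = nt$reason, n = nt$n_samples)
      } else {
        if (!is.null(prefix)) write_network(nt, paste0(prefix, "_net_", nt$group))
        list(skipped = FALSE, n = nt$n_samples,
             mean_abs_r = mean(abs(nt$edges$r)),
             edges = as.list(table(factor(nt$edges$class,
                                          levels = c("strong", "moderate", "none")))))
      }
    })
  }

  trees <- run_stage("cluster", {
    if (is.null(networks)) {
      networks <- lapply(unique(data$group), function(g) {
        build_network(data, g, strong_thr = config$strong_thr,
                      moderate_thr = config$moderate_thr, min_n = config$min_n)
      })
      names(networks) <- unique(data$group)
    }
    usable <- names(networks)[!vapply(networks, function(x) isTRUE(x$skipped), logical(1))]
    tr <- lapply(usable, function(g) {
      d <- correlation_distance(networks[[g]]$corr, mode = config$cluster_mode)
      hierarchical_cluster(d, linkage = config$linkage)
    })
    names(tr) <- usable
    tr
  })
  if (!is.null(trees)) {
    report$clustering <- lapply(names(trees), function(g) {
      if (!is.null(prefix)) {
        as_newick(trees[[g]], file = paste0(prefix, "_tree_", g, ".nwk"))
        write_merge_table(trees[[g]], paste0(prefix, "_merges_", g, ".tsv"))
      }
      list(group = g, newick = as_newick(trees[[g]]))
    })
  }

  model <- run_stage("model", interaction_analysis(
    data, config$case_group, config$control_group,
    alpha_grid = config$alpha_grid, n_lambda = config$n_lambda,
    lambda_min_ratio = config$lambda_min_ratio,
    include_age = config$include_age))
  if (!is.null(model)) {
    if (!is.null(prefix)) {
      write_interaction_table(model$table, paste0(prefix, "_coef"))
      jsonlite::write_json(list(alpha = model$cv$best_alpha,
                                lambda = model$cv$best_lambda,
                                deviance = model$fit$deviance,
                                converged = model$fit$converged,
                                active_set = model$fit$active_set),
                           paste0(prefix, "_fit.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    report$model <- list(alpha = model$cv$best_alpha,
                         lambda = model$cv$best_lambda,
                         deviance = model$fit$deviance,
                         converged = model$fit$converged,
                         active_set = model$fit$active_set)
    if ("diagnostics" %in% config$stages) {
      if (!is.null(prefix)) write_diagnostics(model$diagnostics, prefix)
      report$diagnostics <- list(hl_statistic = model$diagnostics$hl_statistic,
                                 hl_df = model$diagnostics$hl_df,
                                 hl_p = model$diagnostics$hl_p,
                                 auc = model$diagnostics$auc)
    }
  }

  ratio <- run_stage("ratio", ratio_profile(data, config$ratio_num,
                                            config$ratio_den,
                                            reference_group = config$control_group))
  if (!is.null(ratio)) {
    if (!is.null(prefix)) write_ratio_profile(ratio, prefix)
    report$ratio <- list(num_gene = ratio$num_gene, den_gene = ratio$den_gene,
                         summary = ratio$summary,
                         comparisons = ratio$comparisons)
  }

  report$warnings <- warnings_seen
  if (!is.null(prefix)) {
    jsonlite::write_json(report, paste0(prefix, "_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
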