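#' @title Pipeline orchestration
#' @description One-call run of the whole analysis — simulate (or load)
#'   inputs, classify FF/FP/PP patterns, clusters and trajectories, estimate
#'   Ka/Ks, regress r' on Ks, run the randomized-pair null, and build the
#'   co-expression network — writing every result table plus a
#'   machine-readable run summary.
#' @name cli_pipeline
NULL

#' Run configuration
#'
#' Collects every threshold and knob of the pipeline. Serializes losslessly
#' to JSON via [write_run_config()] / [read_run_config()]. The WGCNA module
#' parameters `min_module_size` and `merge_cut_height` are recorded for
#' provenance only; module detection itself is not part of the pipeline.
#'
#' @param simulation `simulation_config` used when no input paths are given.
#' @param pairs_path,expression_path,de_path,tf_path Optional input files;
#'   when all are `NULL` the dataset is simulated.
#' @param alpha,lfc DE-call thresholds (padj < alpha, |log2FC| > lfc).
#' @param r_coexpr Co-expression threshold on within-pair r.
#' @param power,edge_w_min,node_r_min Network soft-threshold power and
#'   edge/node filters.
#' @param min_module_size,merge_cut_height Provenance-only WGCNA parameters.
#' @param rescale_mode `"printed"` or `"fisher"` r' reading.
#' @param statistic `"median"` or `"mean"` permutation summary.
#' @param n_reps Permutation replicates.
#' @param analysis_time_index Time index used for single-condition pattern
#'   calls (default 3, the last point of each course).
#' @param seed Seed for the permutation stage (the simulation carries its
#'   own seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       pairs_path = NULL, expression_path = NULL,
                       de_path = NULL, tf_path = NULL,
                       alpha = 0.05, lfc = 1, r_coexpr = 0.5,
                       power = 10, edge_w_min = 0.3, node_r_min = 0.5,
                       min_module_size = 30, merge_cut_height = 0.25,
                       rescale_mode = c("printed", "fisher"),
                       statistic = c("median", "mean"),
                       n_reps = 1000L, analysis_time_index = 3L,
                       seed = 1L) {
  rescale_mode <- match.arg(rescale_mode)
  statistic <- match.arg(statistic)
  stopifnot(alpha > 0, alpha <= 1, lfc >= 0, r_coexpr >= -1, r_coexpr <= 1,
            power >= 1, edge_w_min >= 0, edge_w_min <= 1,
            node_r_min >= 0, node_r_min <= 1, n_reps >= 1,
            analysis_time_index %in% 1:3)
  structure(list(simulation = simulation, pairs_path = pairs_path,
                 expression_path = expression_path, de_path = de_path,
                 tf_path = tf_path, alpha = alpha, lfc = lfc,
                 r_coexpr = r_coexpr, power = power,
                 edge_w_min = edge_w_min, node_r_min = node_r_min,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 rescale_mode = rescale_mode, statistic = statistic,
                 n_reps = as.integer(n_reps),
                 analysis_time_index = as.integer(analysis_time_index),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to JSON
#' @param config `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path written by [write_run_config()].
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(simulation_config, x$simulation)
  x$simulation <- NULL
  do.call(run_config, c(list(simulation = sim), x))
}

.load_inputs <- function(config) {
  from_files <- !is.null(config$pairs_path)
  if (from_files) {
    pairs <- read_pair_fasta(config$pairs_path)
    expr <- if (!is.null(config$expression_path))
      read_expression_tsv(config$expression_path) else NULL
    de <- if (!is.null(config$de_path)) read_de_tsv(config$de_path) else NULL
    tf_ids <- if (!is.null(config$tf_path)) read_tf_list(config$tf_path)
              else character()
    list(pairs = pairs, expression = expr, de = de, tf_ids = tf_ids,
         source = "files")
  } else {
    sim <- simulate_dataset(config$simulation)
    list(pairs = sim$pairs, expression = sim$expression, de = sim$de,
         tf_ids = sim$tf_ids, source = "simulation")
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full paralog-divergence pipeline
#'
#' Stages: load or simulate inputs; Ka/Ks estimation; FF/FP/PP pattern
#' calls; stress-sharing clusters; enhancing/decreasing trajectories;
#' within-pair correlation, r' rescaling and regression on Ks (over pairs
#' that are FF or FP in at least one condition — the differentially
#' expressed paralogs); randomized-pair permutation tests for FF and FP
#' median Ka/Ks; thresholded co-expression network of DE genes and TFs.
#' Stages without usable input (e.g. no DEPs when `de_fraction = 0`) are
#' skipped with the reason recorded in the summary.
#'
#' @param config `run_config`.
#' @param out_dir Output directory; receives `kaks.tsv, patterns.tsv,
#'   clusters.tsv, trajectories.tsv, regression.json, permutation.json,
#'   network.tsv, summary.json`.
#' @return The run summary (list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- list()
  inputs <- .stage("inputs", .load_inputs(config))
  pairs <- inputs$pairs

  kk <- .stage("kaks", kaks(pairs))
  .write_result_tsv(kk, file.path(out_dir, "kaks.tsv"))

  calls <- .stage("classify", classify_pairs(pairs, inputs$de,
                                             alpha = config$alpha,
                                             lfc = config$lfc))
  .write_result_tsv(calls, file.path(out_dir, "patterns.tsv"))
  counts <- pattern_counts(calls)

  at <- stats::setNames(rep(config$analysis_time_index,
                            length(unique(calls$stress))),
                        unique(calls$stress))
  clusters <- do.call(rbind, lapply(c("FF", "FP"), function(f) {
    cp <- cluster_pairs(calls, f, analysis_time = at)
    if (nrow(cp)) data.frame(focal = f, cp, stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(clusters))
    clusters <- data.frame(focal = character(), pair_id = character(),
                           cluster = character(), stringsAsFactors = FALSE)
  .write_result_tsv(clusters, file.path(out_dir, "clusters.tsv"))

  traj <- .stage("trajectories", trajectory_calls(calls))
  .write_result_tsv(traj, file.path(out_dir, "trajectories.tsv"))

  # DEPs: pairs FF or FP at the analysis time point of any stress
  at_calls <- calls[calls$time_index == config$analysis_time_index, ,
                    drop = FALSE]
  dep_ids <- unique(at_calls$pair_id[at_calls$pattern %in% c("FF", "FP")])
  ff_ids <- unique(at_calls$pair_id[at_calls$pattern == "FF"])
  fp_ids <- unique(at_calls$pair_id[at_calls$pattern == "FP"])

  regression <- NULL
  if (length(dep_ids) >= 3L && !is.null(inputs$expression)) {
    dep_pairs <- pairs[pairs$pair_id %in% dep_ids, , drop = FALSE]
    cors <- .stage("correlate", pair_correlations(dep_pairs,
                                                  inputs$expression))
    rp <- ifelse(!is.na(cors$r) & abs(cors$r) < 1,
                 rescale_r(ifelse(abs(cors$r) < 1, cors$r, 0),
                           mode = config$rescale_mode), NA_real_)
    ksv <- kk$Ks[match(dep_pairs$pair_id, kk$pair_id)]
    regression <- .stage("regression", regress_rprime_on_ks(rp, ksv))
    coex <- .stage("coexpressed",
                   coexpressed_fraction(dep_pairs, inputs$expression,
                                        r_threshold = config$r_coexpr))
    jsonlite::write_json(
      list(slope = regression$slope, intercept = regression$intercept,
           p_slope = regression$p_slope, r_squared = regression$r_squared,
           n = regression$n, n_excluded = regression$n_excluded,
           rescale_mode = config$rescale_mode,
           coexpressed_fraction = as.numeric(coex)),
      file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA)
  } else {
    skipped$regression <- "fewer than 3 differentially expressed paralog pairs"
    coex <- NA_real_
  }

  stat <- paste0(config$statistic, "_ka_ks")
  perms <- list()
  for (cls in c("FF", "FP")) {
    ids <- if (cls == "FF") ff_ids else fp_ids
    obs <- kk[kk$pair_id %in% ids, , drop = FALSE]
    if (nrow(obs) >= 1L && any(!is.na(obs$ka_ks))) {
      pr <- .stage(paste0("permutation_", cls),
                   permutation_test(obs, kk, statistic = stat,
                                    n_reps = config$n_reps,
                                    tail = "greater",
                                    seed = config$seed + match(cls,
                                                               c("FF", "FP"))))
      perms[[cls]] <- list(observed = pr$observed,
                           empirical_p = pr$empirical_p, tail = pr$tail,
                           n_observed = pr$n_observed, n_reps = pr$n_reps)
    } else {
      skipped[[paste0("permutation_", cls)]] <-
        paste("no", cls, "pairs with defined Ka/Ks")
    }
  }
  jsonlite::write_json(perms, file.path(out_dir, "permutation.json"),
                       auto_unbox = TRUE, digits = NA)

  net_summary <- list(nodes = 0L, edges = 0L)
  de_genes <- character()
  if (!is.null(inputs$de) && nrow(inputs$de) > 0L) {
    pass <- .de_call_vec(inputs$de, config$alpha, config$lfc)
    de_genes <- unique(inputs$de$gene[pass])
  }
  net_genes <- unique(c(de_genes, intersect(inputs$tf_ids,
                                            rownames(inputs$expression$values))))
  if (length(net_genes) >= 2L && !is.null(inputs$expression)) {
    adj <- .stage("network", build_adjacency(inputs$expression, net_genes,
                                             power = config$power))
    net <- threshold_network(adj, node_r_min = config$node_r_min,
                             edge_w_min = config$edge_w_min)
    .write_result_tsv(net$edges, file.path(out_dir, "network.tsv"))
    fc <- attr(net, "filter_counts")
    net_summary <- as.list(fc)
  } else {
    skipped$network <- "fewer than 2 differentially expressed or TF genes"
    .write_result_tsv(data.frame(gene_a = character(), gene_b = character(),
                                 r = numeric(), weight = numeric()),
                      file.path(out_dir, "network.tsv"))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("paradiverge")),
    input_source = inputs$source,
    n_pairs = nrow(pairs),
    thresholds = list(alpha = config$alpha, lfc = config$lfc,
                      r_coexpr = config$r_coexpr, power = config$power,
                      edge_w_min = config$edge_w_min,
                      node_r_min = config$node_r_min,
                      min_module_size = config$min_module_size,
                      merge_cut_height = config$merge_cut_height,
                      rescale_mode = config$rescale_mode,
                      statistic = config$statistic,
                      analysis_time_index = config$analysis_time_index),
    seeds = list(pipeline = config$seed,
                 simulation = if (inputs$source == "simulation")
                   config$simulation$seed else NULL),
    n_undefined_ka_ks = sum(is.na(kk$ka_ks)),
    pattern_counts = counts,
    n_dep_pairs = length(dep_ids),
    coexpressed_fraction = if (is.na(coex)) NULL else as.numeric(coex),
    regression = if (is.null(regression)) NULL else
      list(slope = regression$slope, p_slope = regression$p_slope,
           n = regression$n),
    permutation = perms,
    network = net_summary,
    skipped = skipped
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
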