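#' @title Soft-thresholded co-expression network
#' @description Builds the display network of differentially expressed
#'   paralogs and transcription factors: adjacency weights are `|r|^power`
#'   (soft-threshold power 10 by default), edges below weight 0.3 are
#'   removed, then nodes whose strongest remaining correlation falls below
#'   0.5. Module detection (minimum module size, merge cut height) is out of
#'   scope; those WGCNA parameters are recorded in the run configuration
#'   for provenance only.
#' @name coexpression_network
NULL

#' Build a soft-thresholded adjacency
#'
#' For each unordered gene pair, weight = `|r|^power` with r the Pearson
#' correlation of log expression across the selected treated samples.
#' Zero-variance genes produce undefined correlations and no edge.
#'
#' @param expr `expression_matrix`.
#' @param genes Gene IDs to include (must be rows of `expr`).
#' @param power Soft-threshold exponent (>= 1, default 10).
#' @param stress Single stress restricting samples, or `NULL` for all
#'   treated samples.
#' @return Object of class `coexpr_adjacency`: edge data frame
#'   `gene_a, gene_b, r, weight` plus the node set.
#' @export
build_adjacency <- function(expr, genes, power = 10, stress = NULL) {
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  meta <- expr$sample_meta
  keep <- !meta$is_control
  if (!is.null(stress)) keep <- keep & meta$stress == stress
  cols <- meta$sample[keep]
  if (length(cols) < 3L)
    stop("need at least 3 samples to build an adjacency", call. = FALSE)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  genes <- unique(genes)
  m <- t(log(expr$values[genes, cols, drop = FALSE] + 1))
  sds <- apply(m, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(m))
  edges <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[edges]
  ok <- is.finite(r) & sds[edges[, 1L]] > 0 & sds[edges[, 2L]] > 0
  out <- data.frame(gene_a = genes[edges[ok, 1L]],
                    gene_b = genes[edges[ok, 2L]],
                    r = r[ok], weight = abs(r[ok])^power,
                    stringsAsFactors = FALSE)
  structure(list(edges = out, nodes = genes, power = power),
            class = "coexpr_adjacency")
}

#' Threshold an adjacency into a co-expression network
#'
#' Applies the published display filters in order: edges with weight below
#' `edge_w_min` are removed first, then nodes whose maximum `|r|` to any
#' other retained node is below `node_r_min` (nodes left without edges are
#' removed too). The operation is idempotent. An empty network is a valid
#' result.
#'
#' @param adjacency `coexpr_adjacency` (or a `coexpression_network`, which
#'   is re-thresholded).
#' @param node_r_min Node correlation threshold (default 0.5).
#' @param edge_w_min Edge weight threshold (default 0.3).
#' @return Object of class `coexpression_network`: `nodes` data frame
#'   (`gene, is_tf, pattern_label, direction`), `edges` data frame, and
#'   before/after counts in attribute `"filter_counts"`.
#' @export
threshold_network <- function(adjacency, node_r_min = 0.5, edge_w_min = 0.3) {
  edges <- adjacency$edges
  nodes_before <- if (!is.null(adjacency$nodes)) {
    if (is.data.frame(adjacency$nodes)) adjacency$nodes$gene else adjacency$nodes
  } else unique(c(edges$gene_a, edges$gene_b))
  n_edges_before <- nrow(edges)
  edges <- edges[edges$weight >= edge_w_min, , drop = FALSE]
  repeat {
    node_max_r <- tapply(c(abs(edges$r), abs(edges$r)),
                         c(edges$gene_a, edges$gene_b), max)
    keep_nodes <- names(node_max_r)[node_max_r >= node_r_min]
    keep_edge <- edges$gene_a %in% keep_nodes & edges$gene_b %in% keep_nodes
    if (all(keep_edge)) break
    edges <- edges[keep_edge, , drop = FALSE]
  }
  retained <- if (nrow(edges)) sort(unique(c(edges$gene_a, edges$gene_b)))
              else character()
  nodes <- data.frame(gene = retained,
                      is_tf = rep(FALSE, length(retained)),
                      pattern_label = rep("none", length(retained)),
                      direction = rep("none", length(retained)),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  out <- structure(list(nodes = nodes, edges = edges,
                        node_r_min = node_r_min, edge_w_min = edge_w_min),
                   class = "coexpression_network")
  attr(out, "filter_counts") <- c(nodes_before = length(nodes_before),
                                  nodes_after = nrow(nodes),
                                  edges_before = n_edges_before,
                                  edges_after = nrow(edges))
  out
}

#' @export
print.coexpression_network <- function(x, ...) {
  fc <- attr(x, "filter_counts")
  cat(sprintf("Co-expression network: %d nodes, %d edges", nrow(x$nodes),
              nrow(x$edges)))
  if (!is.null(fc))
    cat(sprintf(" (from %d nodes / %d edges before thresholding)",
                fc[["nodes_before"]], fc[["edges_before"]]))
  cat("\n")
  if (nrow(x$nodes) == 0) cat("  (empty network)\n")
  invisible(x)
}

#' Annotate a network with TF/DEP labels and rank co-expressed TFs
#'
#' Flags transcription-factor nodes, attaches trajectory pattern labels and
#' regulation directions to differentially expressed paralog (DEP) nodes,
#' counts each TF's DEP neighbors (optionally aggregated by TF family), and
#' compares DEP-TF edge counts between enhancing and decreasing subsets.
#'
#' @param network `coexpression_network`.
#' @param tf_ids Character vector of TF gene IDs.
#' @param family Optional named character vector mapping TF gene -> family
#'   label (e.g. MYB/ERF/bHLH).
#' @param dep_labels Optional data frame `gene, pattern_label, direction`
#'   with pattern_label in enhancing/decreasing/none and direction in
#'   up/down/none.
#' @return List of class `network_annotation`: annotated `network`,
#'   `tf_ranking` (TF, family, DEP-neighbor count, descending),
#'   `family_ranking`, and `dep_tf_edges_by_pattern`.
#' @export
annotate_and_count <- function(network, tf_ids, family = NULL,
                               dep_labels = NULL) {
  nodes <- network$nodes
  nodes$is_tf <- nodes$gene %in% tf_ids
  if (!is.null(dep_labels)) {
    i <- match(nodes$gene, dep_labels$gene)
    nodes$pattern_label <- ifelse(is.na(i), "none", dep_labels$pattern_label[i])
    nodes$direction <- ifelse(is.na(i), "none", dep_labels$direction[i])
  }
  network$nodes <- nodes
  edges <- network$edges
  is_tf_a <- edges$gene_a %in% tf_ids
  is_tf_b <- edges$gene_b %in% tf_ids
  # TF-DEP edges: exactly one endpoint is a TF
  mixed <- xor(is_tf_a, is_tf_b)
  tf_of <- ifelse(is_tf_a, edges$gene_a, edges$gene_b)[mixed]
  dep_of <- ifelse(is_tf_a, edges$gene_b, edges$gene_a)[mixed]
  tfs_in_net <- nodes$gene[nodes$is_tf]
  if (length(tfs_in_net)) {
    cnt <- table(factor(tf_of, levels = tfs_in_net))
    tf_ranking <- data.frame(tf = names(cnt),
                             dep_neighbors = as.integer(cnt),
                             stringsAsFactors = FALSE)
    tf_ranking$family <- if (!is.null(family)) {
      fam <- family[tf_ranking$tf]
      ifelse(is.na(fam), "unknown", fam)
    } else "unknown"
    tf_ranking <- tf_ranking[order(-tf_ranking$dep_neighbors, tf_ranking$tf), ]
    rownames(tf_ranking) <- NULL
    fam_cnt <- tapply(tf_ranking$dep_neighbors, tf_ranking$family, sum)
    family_ranking <- data.frame(family = names(fam_cnt),
                                 dep_neighbors = as.integer(fam_cnt),
                                 stringsAsFactors = FALSE)
    family_ranking <- family_ranking[order(-family_ranking$dep_neighbors,
                                           family_ranking$family), ]
    rownames(family_ranking) <- NULL
  } else {
    tf_ranking <- data.frame(tf = character(), dep_neighbors = integer(),
                             family = character(), stringsAsFactors = FALSE)
    family_ranking <- data.frame(family = character(),
                                 dep_neighbors = integer(),
                                 stringsAsFactors = FALSE)
  }
  pat_counts <- c(enhancing = 0L, decreasing = 0L)
  if (!is.null(dep_labels) && length(dep_of)) {
    i <- match(dep_of, dep_labels$gene)
    pat <- ifelse(is.na(i), "none", dep_labels$pattern_label[i])
    pat_counts["enhancing"] <- sum(pat == "enhancing")
    pat_counts["decreasing"] <- sum(pat == "decreasing")
  }
  structure(list(network = network, tf_ranking = tf_ranking,
                 family_ranking = family_ranking,
                 dep_tf_edges_by_pattern = pat_counts),
            class = "network_annotation")
}

#' @export
print.network_annotation <- function(x, ...) {
  print(x$network)
  cat("Top co-expressed TFs by DEP neighbors:\n")
  print(utils::head(x$tf_ranking, 5), row.names = FALSE)
  cat(sprintf("DEP-TF edges: %d enhancing vs %d decreasing\n",
              x$dep_tf_edges_by_pattern[["enhancing"]],
              x$dep_tf_edges_by_pattern[["decreasing"]]))
  invisible(x)
}
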