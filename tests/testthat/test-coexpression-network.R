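# helper: expression matrix with an exact target correlation structure is
# hard to pin; instead build adjacency objects directly for threshold tests.
adj_from_edges <- function(edges, power = 10) {
  edges$weight <- abs(edges$r)^power
  structure(list(edges = edges,
                 nodes = unique(c(edges$gene_a, edges$gene_b)),
                 power = power),
            class = "coexpr_adjacency")
}

test_that("soft-threshold weights follow |r|^power", {
  # g2 + 1 = 2 * (g1 + 1): exactly collinear on the log(x + 1) scale
  m <- matrix(c(1, 2, 4, 3, 5, 9, 3, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("Dr_1_1", "Dr_2_1", "Dr_3_1")))
  adj <- build_adjacency(toy_expression(m), c("g1", "g2", "g3"), power = 10)
  e12 <- adj$edges[adj$edges$gene_a == "g1" & adj$edges$gene_b == "g2", ]
  expect_equal(e12$weight, 1)
  # zero-variance gene g3 contributes no edges
  expect_false("g3" %in% c(adj$edges$gene_a, adj$edges$gene_b))
  expect_error(build_adjacency(toy_expression(m), "g1", power = 0.5),
               "power")
  expect_error(build_adjacency(toy_expression(m[, 1:2]), c("g1", "g2")),
               "3 samples")
  expect_equal(round(0.9^10, 5), 0.34868)
  expect_equal(round(0.8^10, 5), 0.10737)
})

test_that("thresholding keeps strong edges and drops weak nodes", {
  edges <- data.frame(gene_a = c("a", "a", "b"),
                      gene_b = c("b", "c", "c"),
                      r = c(1, 1, 1), stringsAsFactors = FALSE)
  full <- threshold_network(adj_from_edges(edges))
  expect_equal(nrow(full$edges), 3L)
  expect_equal(nrow(full$nodes), 3L)

  weak <- edges
  weak$r <- 0.4
  empty <- threshold_network(adj_from_edges(weak))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)

  # r = 0.9: weight 0.349 survives the edge filter; r = 0.8: 0.107 does not
  mixed <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      r = c(0.9, 0.8), stringsAsFactors = FALSE)
  net <- threshold_network(adj_from_edges(mixed))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$r, 0.9)
  # c lost its only (weak) edge and is dropped with it
  expect_setequal(net$nodes$gene, c("a", "b"))
  expect_true(all(net$edges$weight >= 0.3 & net$edges$weight <= 1))
})

test_that("a node whose strong edge is removed by the edge filter cascades out", {
  # b-c survives the edge filter; a's only edge (r = 0.85, weight ~ 0.197)
  # is removed, so a leaves the network even though |r| = 0.85 > 0.5
  toy <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                    r = c(0.85, 0.95), stringsAsFactors = FALSE)
  net <- threshold_network(adj_from_edges(toy))
  expect_setequal(net$nodes$gene, c("b", "c"))
  expect_equal(nrow(net$edges), 1L)
})

test_that("thresholding is idempotent", {
  set.seed(17)
  rs <- runif(40, -1, 1)
  edges <- data.frame(gene_a = sample(letters[1:12], 40, replace = TRUE),
                      gene_b = sample(letters[13:24], 40, replace = TRUE),
                      r = rs, stringsAsFactors = FALSE)
  once <- threshold_network(adj_from_edges(edges))
  twice <- threshold_network(once)
  expect_equal(twice$edges, once$edges)
  expect_equal(twice$nodes, once$nodes)
})

test_that("TF ranking counts DEP neighbors and compares pattern classes", {
  edges <- data.frame(
    gene_a = c("tf1", "tf1", "tf1", "tf2", "dep1"),
    gene_b = c("dep1", "dep2", "dep3", "dep1", "dep2"),
    r = 0.95, stringsAsFactors = FALSE)
  net <- threshold_network(adj_from_edges(edges, power = 1),
                           edge_w_min = 0.3, node_r_min = 0.5)
  labels <- data.frame(gene = c("dep1", "dep2", "dep3"),
                       pattern_label = c("enhancing", "enhancing",
                                         "decreasing"),
                       direction = c("up", "down", "up"),
                       stringsAsFactors = FALSE)
  ann <- annotate_and_count(net, tf_ids = c("tf1", "tf2"),
                            family = c(tf1 = "MYB", tf2 = "ERF"),
                            dep_labels = labels)
  expect_equal(ann$tf_ranking$tf, c("tf1", "tf2"))
  expect_equal(ann$tf_ranking$dep_neighbors, c(3L, 1L))
  expect_equal(ann$family_ranking$family[1], "MYB")
  expect_equal(unname(ann$dep_tf_edges_by_pattern["enhancing"]), 3L)
  expect_equal(unname(ann$dep_tf_edges_by_pattern["decreasing"]), 1L)
  # no TFs -> empty ranking
  none <- annotate_and_count(net, tf_ids = character())
  expect_equal(nrow(none$tf_ranking), 0L)
})

test_that("a planted hub TF is recovered as top-ranked", {
  set.seed(18)
  hits <- vapply(1:50, function(rep) {
    n_dep <- 8
    n_samp <- 12
    hub <- rnorm(n_samp)
    # DEPs track the hub tightly; a decoy TF tracks only one DEP loosely
    deps <- vapply(1:n_dep, function(i) hub + rnorm(n_samp, sd = 0.1),
                   numeric(n_samp))
    decoy <- deps[, 1] + rnorm(n_samp, sd = 1.2)
    m <- exp(3 + t(cbind(hub, decoy, deps)))
    rownames(m) <- c("hub", "decoy", paste0("dep", 1:n_dep))
    colnames(m) <- paste0(rep(c("Dr", "Cd", "Bc", "Pr"), each = 3), "_",
                          rep(1:3, 4), "_1")
    expr <- toy_expression(m)
    adj <- build_adjacency(expr, rownames(m), power = 10)
    net <- threshold_network(adj)
    ann <- annotate_and_count(net, tf_ids = c("hub", "decoy"))
    nrow(ann$tf_ranking) > 0 && ann$tf_ranking$tf[1] == "hub"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
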