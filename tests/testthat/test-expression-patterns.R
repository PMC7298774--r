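test_that("DE calls use strict thresholds", {
  expect_true(call_de(de_rows("g", "Dr", 1, -2, 0.01)))
  expect_false(call_de(de_rows("g", "Dr", 1, 3, 0.05)))    # padj boundary
  expect_false(call_de(de_rows("g", "Dr", 1, 1.0, 0.01)))  # lfc boundary
  expect_false(call_de(de_rows("g", "Dr", 1, 3, 0.01, expressed = FALSE)))
  expect_false(call_de(NULL))
})

test_that("pairs partition into FF/FP/PP by their genes' DE calls", {
  pairs <- rbind(toy_pairs_df("p1"),
                 toy_pairs_df("p2", gene_a = "gC", gene_b = "gD"),
                 toy_pairs_df("p3", gene_a = "gE", gene_b = "gF"))
  de <- rbind(de_rows("gA", "Dr", 1, 2.5, 0.001),   # p1: both DE -> FF
              de_rows("gB", "Dr", 1, -1.5, 0.01),
              de_rows("gC", "Dr", 1, 2.0, 0.001))   # p2: one DE -> FP
  calls <- classify_pairs(pairs, de)
  expect_equal(calls$pattern, c("FF", "FP", "PP"))
  # partition: exactly one pattern per pair x condition
  expect_equal(nrow(calls), 3L)
  expect_true(all(calls$pattern %in% c("FF", "FP", "PP")))
})

test_that("cluster assignment maps the seven named Venn regions", {
  expect_equal(assign_cluster(c("Dr", "Cd", "Bc", "Pr")), "all_four")
  expect_equal(assign_cluster(c("Dr", "Cd")), "abiotic_shared")
  expect_equal(assign_cluster(c("Bc", "Pr")), "biotic_shared")
  expect_equal(assign_cluster("Dr"), "Dr_specific")
  expect_equal(assign_cluster("Pr"), "Pr_specific")
  expect_error(assign_cluster(character()), "empty membership")
  expect_error(assign_cluster("Zz"), "unknown stress")
  # exhaustive: every region outside the named seven goes to "other"
  named <- list(c("Dr", "Cd", "Bc", "Pr"), c("Dr", "Cd"), c("Bc", "Pr"),
                "Dr", "Cd", "Bc", "Pr")
  all_regions <- unlist(lapply(1:4, function(k)
    utils::combn(c("Dr", "Cd", "Bc", "Pr"), k, simplify = FALSE)),
    recursive = FALSE)
  for (reg in all_regions) {
    expected <- if (any(vapply(named, setequal, TRUE, reg))) NA else "other"
    if (!is.na(expected)) expect_equal(assign_cluster(reg), "other")
  }
})

test_that("trajectory classification follows the rank rules", {
  expect_equal(classify_trajectory(c(0, 1, 2)), "enhancing")
  expect_equal(classify_trajectory(c(2, 1, 0)), "decreasing")
  expect_equal(classify_trajectory(c(1, 0, 2)), "mixed")
  expect_equal(classify_trajectory(c(1, 1, 1)), "stable")
  expect_equal(classify_trajectory(c(2, 2, 2)), "stable")  # no change, not decreasing
  expect_equal(classify_trajectory(c(0, 2, 2)), "enhancing")
  expect_equal(classify_trajectory(c(2, 2, 1)), "decreasing")
  expect_error(classify_trajectory(c(0, 1, 3)), "ranks")
  # label invariance: reversing time swaps enhancing and decreasing
  grid <- expand.grid(r1 = 0:2, r2 = 0:2, r3 = 0:2)
  swap <- c(enhancing = "decreasing", decreasing = "enhancing",
            stable = "stable", mixed = "mixed")
  for (i in seq_len(nrow(grid))) {
    fwd <- classify_trajectory(unlist(grid[i, ]))
    rev <- classify_trajectory(rev(unlist(grid[i, ])))
    expect_equal(rev, unname(swap[fwd]))
  }
})

test_that("pattern counts sum to the number of pairs per condition", {
  pairs <- toy_pairs_df(sprintf("p%02d", 1:10),
                        gene_a = sprintf("g%02da", 1:10),
                        gene_b = sprintf("g%02db", 1:10))
  calls <- classify_pairs(pairs, de_rows("none", "Dr", 1, 0, 1),
                          stresses = "Dr", time_indices = 1L)
  counts <- pattern_counts(calls)
  expect_equal(counts$PP, 10L)
  expect_equal(counts$FF + counts$FP + counts$PP, counts$n)
  expect_equal(counts$n, 10L)
})

test_that("co-expressed fraction handles perfect and anti correlation", {
  base <- matrix(rep(c(1, 2, 4, 8), each = 2), nrow = 2, byrow = FALSE,
                 dimnames = list(c("gA", "gB"),
                                 c("Dr_1_1", "Dr_2_1", "Dr_3_1", "Cd_1_1")))
  pairs <- toy_pairs_df("p1")
  expect_equal(coexpressed_fraction(pairs, toy_expression(base)),
               1.0, ignore_attr = TRUE)

  anti <- base
  anti["gB", ] <- rev(exp(log(base["gB", ])))  # reversed -> negative r
  expect_equal(coexpressed_fraction(pairs, toy_expression(anti)),
               0.0, ignore_attr = TRUE)
  expect_error(coexpressed_fraction(pairs[0, ], toy_expression(base)),
               "empty")
})

test_that("planted enhancing/decreasing trajectories are recovered exactly", {
  cfg <- simulation_config(n_pairs = 120, de_fraction = 0.3,
                           enhancing_fraction = 0.25,
                           decreasing_fraction = 0.15, seed = 31)
  sim <- simulate_dataset(cfg)
  calls <- classify_pairs(sim$pairs, sim$de)
  traj <- trajectory_calls(calls)
  planted <- sim$planted
  for (st in unique(traj$stress)) {
    sub <- traj[traj$stress == st, ]
    lab <- planted$planted[match(sub$pair_id, planted$pair_id)]
    expect_true(all(sub$trajectory[lab == "enhancing"] == "enhancing"))
    expect_true(all(sub$trajectory[lab == "decreasing"] == "decreasing"))
  }
})
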