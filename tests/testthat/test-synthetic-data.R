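test_that("ancestral CDS contains only sense codons", {
  set.seed(5)
  expect_error(generate_ancestral_cds(0), ">= 1")
  one <- generate_ancestral_cds(1)
  expect_equal(nchar(one), 3L)
  expect_false(oracle_translate_codon(one) == "*")
  # property: no stop anywhere over many draws (translation oracle)
  for (i in 1:200) {
    cds <- generate_ancestral_cds(sample(1:30, 1))
    aa <- seqinr::translate(strsplit(cds, "")[[1]])
    expect_false(any(aa == "*"))
  }
})

test_that("sequence generation is deterministic under a fixed seed", {
  set.seed(99)
  a <- generate_ancestral_cds(100)
  set.seed(99)
  b <- generate_ancestral_cds(100)
  expect_identical(a, b)
})

test_that("evolve_pair honors target_ks = 0 and omega = 0 limits", {
  set.seed(1)
  anc <- generate_ancestral_cds(50)
  p0 <- evolve_pair(anc, omega = 0.5, target_ks = 0)
  expect_identical(p0$cds_a, anc)
  expect_identical(p0$cds_b, anc)

  # omega -> 0: nonsynonymous proposals essentially never accepted
  p <- evolve_pair(anc, omega = 1e-12, target_ks = 0.3)
  expect_equal(compute_ka_ks(p$cds_a, p$cds_b)$Nd, 0)
  expect_error(evolve_pair(anc, omega = 0, target_ks = 0.1), "omega")
})

test_that("realized substitution tallies match NG86 estimates at omega = 1", {
  set.seed(21)
  n <- 60
  real_ks <- est_ks <- real_ka <- est_ka <- numeric(n)
  for (i in 1:n) {
    anc <- generate_ancestral_cds(100)
    p <- evolve_pair(anc, omega = 1, target_ks = 0.3)
    ev <- attr(p, "events")
    sn <- count_sites(anc)
    real_ks[i] <- sum(ev$syn) / sn[["S"]]
    real_ka[i] <- sum(ev$nonsyn) / sn[["N"]]
    est <- compute_ka_ks(p$cds_a, p$cds_b)
    est_ks[i] <- est$Ks
    est_ka[i] <- est$Ka
  }
  # JC-corrected estimates track the realized per-site counts within 3 MC sigma
  se_ks <- sd(est_ks - real_ks) / sqrt(n)
  se_ka <- sd(est_ka - real_ka) / sqrt(n)
  expect_lt(abs(mean(est_ks - real_ks)), 3 * se_ks + 0.02)
  expect_lt(abs(mean(est_ka - real_ka)), 3 * se_ka + 0.02)
})

test_that("expression simulation reproduces the Ks-coupled correlation", {
  cfg <- simulation_config(n_pairs = 400, coupling_lambda = 1, seed = 2)
  set.seed(2)
  pairs <- toy_pairs_df(sprintf("p%03d", 1:400),
                        gene_a = sprintf("g%03da", 1:400),
                        gene_b = sprintf("g%03db", 1:400))
  expr <- simulate_expression(pairs, rep(0.5, 400), cfg)
  cors <- pair_correlations(pairs, expr)
  expect_lt(abs(mean(cors$r) - exp(-0.5)), 0.1)

  # lambda = 0: correlations stay near their (noise-attenuated) maximum
  cfg0 <- simulation_config(n_pairs = 100, coupling_lambda = 0, seed = 3)
  set.seed(3)
  p100 <- pairs[1:100, ]
  expr0 <- simulate_expression(p100, seq(0, 5, length.out = 100), cfg0)
  cors0 <- pair_correlations(p100, expr0)
  expect_gt(mean(cors0$r), 0.85)
  # and are unrelated to Ks
  expect_gt(cor.test(cors0$r, seq(0, 5, length.out = 100))$p.value, 0.001)

  expect_error(simulate_expression(p100, rep(0.5, 99), cfg0), "one Ks per")
})

test_that("DE table generation respects threshold structure", {
  pairs <- toy_pairs_df(sprintf("p%03d", 1:125),
                        gene_a = sprintf("g%03da", 1:125),
                        gene_b = sprintf("g%03db", 1:125))
  cfg0 <- simulation_config(n_pairs = 125, de_fraction = 0, seed = 4)
  set.seed(4)
  de0 <- simulate_de_table(pairs, cfg0)
  expect_equal(sum(paradiverge:::.de_call_vec(de0, 0.05, 1)), 0L)

  cfg1 <- simulation_config(n_pairs = 125, de_fraction = 1, effect_mu = 2,
                            seed = 4)
  set.seed(4)
  de1 <- simulate_de_table(pairs, cfg1)
  expect_true(all(paradiverge:::.de_call_vec(de1, 0.05, 1)))

  # de_fraction = 0.3: passing fraction within binomial 3 sigma at n = 3000
  cfg3 <- simulation_config(n_pairs = 125, de_fraction = 0.3, seed = 4)
  set.seed(4)
  de3 <- simulate_de_table(pairs, cfg3)
  frac <- mean(paradiverge:::.de_call_vec(de3, 0.05, 1))
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("a fixed configuration yields byte-identical dataset files", {
  cfg <- simulation_config(n_pairs = 12, codons_per_gene = 30,
                           enhancing_fraction = 0.2, seed = 123)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in c("pairs.fasta", "expression.tsv", "de.tsv", "tf_list.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
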