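test_that("site counting matches hand-enumerated codon examples", {
  # TTT (Phe): only TTC at position 3 is synonymous -> S = 1/3
  expect_equal(count_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  # GGG (Gly): all third-position changes stay Gly -> S = 1
  expect_equal(count_sites("GGG"), c(S = 1, N = 2))
  # site counts partition the length
  for (cds in c("TTT", "ATGAAA", "TTTAAAGGG", "ATGTGGCAT")) {
    sn <- count_sites(cds)
    expect_equal(unname(sn["S"] + sn["N"]), nchar(cds))
  }
})

test_that("site counting rejects invalid CDS", {
  expect_error(count_sites("TTTA"), "multiple of 3")
  expect_error(count_sites("TAA"), "stop codon")
  expect_error(count_sites("TTN"), "ambiguity")
})

test_that("difference counting classifies single changes directly", {
  expect_equal(count_differences("GGG", "GGA"), c(Sd = 1, Nd = 0))
  expect_equal(count_differences("TTT", "TTA"), c(Sd = 0, Nd = 1))
  expect_equal(count_differences("TTTAAA", "TTTAAA"), c(Sd = 0, Nd = 0))
  expect_error(count_differences("TTT", "TTTAAA"), "unequal lengths")
})

test_that("multi-position codons average over substitution pathways", {
  # TTT -> GTA differs at positions 1 and 3; check against brute force
  expect_equal(count_differences("TTT", "GTA"),
               oracle_count_differences("TTT", "GTA"), tolerance = 1e-12)
  # a pair whose direct pathways pass near stop codons
  expect_equal(count_differences("TGTTCA", "TGGTCC"),
               oracle_count_differences("TGTTCA", "TGGTCC"),
               tolerance = 1e-12)
  # three-position difference
  expect_equal(count_differences("AAA", "GGG"),
               oracle_count_differences("AAA", "GGG"), tolerance = 1e-12)
})

test_that("Jukes-Cantor correction behaves over its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.6), -0.75 * log(0.2))
  expect_equal(round(jukes_cantor(0.6), 3), 1.207)
  expect_error(jukes_cantor(0.75), "saturation")
  expect_error(jukes_cantor(-0.1), "p must be")
  # d >= p and monotone on a grid
  p <- seq(0, 0.7, by = 0.05)
  d <- vapply(p, jukes_cantor, 0)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
})

test_that("compute_ka_ks reproduces the worked NG86 example", {
  est <- compute_ka_ks("TTTAAAGGG", "TTTAAAGGA")
  expect_equal(est$S, 5 / 3)
  expect_equal(est$N, 22 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$Ks, -0.75 * log(0.2))
  expect_equal(est$Ka, 0)
  expect_equal(est$ka_ks, 0)
  expect_equal(est$selection, "negative")
})

test_that("degenerate ratios are undefined, not errors", {
  same <- compute_ka_ks(strrep("TTTAAAGGG", 34), strrep("TTTAAAGGG", 34))
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ka_ks))
  expect_equal(same$selection, "undefined")

  nonsyn_only <- compute_ka_ks("TTT", "TTA")
  expect_equal(nonsyn_only$Ks, 0)
  expect_equal(nonsyn_only$Ka, -0.75 * log(1 - (4 / 3) * 0.4))
  expect_true(is.na(nonsyn_only$ka_ks))
})

test_that("estimates are symmetric in the two sequences", {
  set.seed(42)
  for (i in 1:20) {
    anc <- generate_ancestral_cds(15)
    pair <- evolve_pair(anc, omega = 1, target_ks = 0.4)
    ab <- compute_ka_ks(pair$cds_a, pair$cds_b)
    ba <- compute_ka_ks(pair$cds_b, pair$cds_a)
    expect_equal(ab[c("S", "N", "Sd", "Nd", "Ka", "Ks", "ka_ks")],
                 ba[c("S", "N", "Sd", "Nd", "Ka", "Ks", "ka_ks")])
  }
})

test_that("NG86 counting agrees with the brute-force oracle on random pairs", {
  set.seed(7)
  for (i in 1:100) {
    anc <- oracle_random_cds(sample(2:20, 1))
    pair <- evolve_pair(anc, omega = runif(1, 0.2, 2),
                        target_ks = runif(1, 0, 0.8))
    est <- compute_ka_ks(pair$cds_a, pair$cds_b)
    s_or <- oracle_count_sites(pair$cds_a)
    s_or_b <- oracle_count_sites(pair$cds_b)
    d_or <- oracle_count_differences(pair$cds_a, pair$cds_b)
    expect_equal(est$S, unname((s_or["S"] + s_or_b["S"]) / 2),
                 tolerance = 1e-10)
    expect_equal(est$Sd, unname(d_or["Sd"]), tolerance = 1e-10)
    expect_equal(est$Nd, unname(d_or["Nd"]), tolerance = 1e-10)
  }
})

test_that("Ks estimates rise with the simulated divergence target", {
  set.seed(11)
  med_ks <- vapply(c(0.1, 0.5, 1.0), function(tk) {
    ests <- vapply(1:60, function(i) {
      pair <- evolve_pair(generate_ancestral_cds(100), omega = 0.5,
                          target_ks = tk)
      compute_ka_ks(pair$cds_a, pair$cds_b)$Ks
    }, numeric(1))
    median(ests, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_ks) > 0))
})

test_that("batch kaks preserves order and flags undefined ratios", {
  pairs <- rbind(toy_pairs_df("p1"),
                 toy_pairs_df("p2", cds_a = "TTTAAAGGG", cds_b = "TTTAAAGGG"))
  kk <- kaks(pairs)
  expect_equal(kk$pair_id, c("p1", "p2"))
  expect_equal(kk$selection, c("negative", "undefined"))
  expect_output(print(kk), "undefined")
})
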