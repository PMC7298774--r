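#' @title Synthetic paralog-pair data
#' @description Generates paralog pairs (codon sequences, expression matrix,
#'   differential-expression table, TF list) with the statistical structure
#'   the downstream analysis assumes: sequence pairs evolved from a common
#'   ancestor at a chosen selection intensity omega and synonymous divergence
#'   Ks, within-pair expression correlation decaying with Ks as
#'   `rho = exp(-lambda * Ks)`, and DE effect sizes built around the
#'   `padj < 0.05`, `|log2FC| > 1` thresholds.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: 4 stresses
#' (Dr/Cd/Bc/Pr) x 3 time points each, with one control per condition.
#'
#' @param n_pairs Number of paralog pairs.
#' @param codons_per_gene Codons per CDS (default 100).
#' @param omega Target Ka/Ks of the evolutionary process (> 0).
#' @param target_ks Pairwise synonymous divergence: a single value applied to
#'   every pair, a length-2 range sampled uniformly per pair, or a length
#'   `n_pairs` vector.
#' @param coupling_lambda Decay rate lambda >= 0 of the within-pair expression
#'   correlation `rho = exp(-lambda * Ks)`.
#' @param de_fraction Probability a gene is differentially expressed in a
#'   given condition, in `[0, 1]`.
#' @param effect_mu Mean `|log2FC|` of DE genes (> 1).
#' @param enhancing_fraction,decreasing_fraction Fractions of pairs planted
#'   with a monotone trajectory: neither gene DE at the first time point
#'   through both DE at the last (enhancing), or the reverse (decreasing).
#' @param replicates Treated replicates per condition (default 1).
#' @param noise_sd Standard deviation of independent per-observation
#'   measurement noise on the log scale (default 0.2). Without it the
#'   within-pair correlation would be exactly `rho` (degenerate r = 1 at
#'   `lambda = 0`), leaving nothing for the correlation estimate to
#'   estimate.
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @param baseline_log_mean Mean of log-expression at baseline (FPKM-like
#'   after exponentiation; default 3, about 20 FPKM).
#' @param n_timepoints Time points per stress (fixed design: 3).
#' @param stresses Stress codes (fixed design: Dr, Cd, Bc, Pr).
#' @param seed RNG seed; identical configurations produce byte-identical
#'   output files.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 300L, codons_per_gene = 100L,
                              omega = 0.5, target_ks = c(0.05, 1.5),
                              coupling_lambda = 1, de_fraction = 0.3,
                              effect_mu = 2, enhancing_fraction = 0,
                              decreasing_fraction = 0, replicates = 1L,
                              noise_sd = 0.2,
                              tf_fraction = 0.1, baseline_log_mean = 3,
                              n_timepoints = 3L, stresses = .STRESSES,
                              seed = 1L) {
  stopifnot(n_pairs >= 1, codons_per_gene >= 1, omega > 0,
            all(target_ks >= 0), coupling_lambda >= 0,
            de_fraction >= 0, de_fraction <= 1, effect_mu > 1,
            enhancing_fraction >= 0, decreasing_fraction >= 0,
            enhancing_fraction + decreasing_fraction <= 1,
            replicates >= 1, noise_sd >= 0,
            tf_fraction >= 0, tf_fraction <= 1,
            n_timepoints == 3L)
  structure(list(n_pairs = as.integer(n_pairs),
                 codons_per_gene = as.integer(codons_per_gene),
                 omega = omega, target_ks = target_ks,
                 coupling_lambda = coupling_lambda,
                 de_fraction = de_fraction, effect_mu = effect_mu,
                 enhancing_fraction = enhancing_fraction,
                 decreasing_fraction = decreasing_fraction,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd,
                 tf_fraction = tf_fraction,
                 baseline_log_mean = baseline_log_mean,
                 n_timepoints = 3L, stresses = stresses,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a random ancestral CDS
#'
#' Uniform random sense codons (the 61 non-stop codons of the standard code).
#'
#' @param codons Number of codons (>= 1).
#' @return Nucleotide string of length `3 * codons` with no stop codons.
#' @export
generate_ancestral_cds <- function(codons) {
  if (!is.numeric(codons) || length(codons) != 1L || codons < 1)
    stop("codons must be >= 1", call. = FALSE)
  sense <- setdiff(seq_len(64L), .STOP_IDS)
  ids <- sense[sample.int(length(sense), codons, replace = TRUE)]
  paste(vapply(ids, function(id) .int_to_seq(.codon_id_to_triplet(id)), ""),
        collapse = "")
}

# evolve one lineage to target synonymous substitutions per NG86 synonymous
# site; returns list(seq = int vector, syn = count, nonsyn = count)
.evolve_lineage <- function(anc, omega, target, max_prop) {
  v <- anc
  L <- length(v)
  s_cur <- sum(.SYN_FRAC[.codon_ids(v)])
  syn_n <- 0L; nonsyn_n <- 0L
  if (target <= 0) return(list(seq = v, syn = 0L, nonsyn = 0L))
  p_syn <- if (omega > 1) 1 / omega else 1
  p_non <- if (omega > 1) 1 else omega
  prop <- 0L
  while (syn_n / s_cur < target) {
    prop <- prop + 1L
    if (prop > max_prop)
      stop("saturation guard: target synonymous divergence unreachable ",
           "after ", max_prop, " proposals", call. = FALSE)
    pos <- sample.int(L, 1L)
    new_nt <- sample.int(4L, 1L)
    if (new_nt == v[pos]) next
    cs <- pos - (pos - 1L) %% 3L  # codon start
    trip <- v[cs:(cs + 2L)]
    old_id <- .triplet_to_codon_id(trip)
    trip[(pos - cs) + 1L] <- new_nt
    new_id <- .triplet_to_codon_id(trip)
    if (.AA[new_id] == "*") next  # stop codons never fix
    syn <- .AA[new_id] == .AA[old_id]
    p_acc <- if (syn) p_syn else p_non
    if (p_acc < 1 && stats::runif(1L) >= p_acc) next
    v[pos] <- new_nt
    s_cur <- s_cur + .SYN_FRAC[new_id] - .SYN_FRAC[old_id]
    if (syn) syn_n <- syn_n + 1L else nonsyn_n <- nonsyn_n + 1L
  }
  list(seq = v, syn = syn_n, nonsyn = nonsyn_n)
}

#' Evolve a paralog pair from an ancestral CDS
#'
#' Each descendant lineage evolves independently by iterated single-nucleotide
#' proposals: proposals creating a stop codon are rejected; for `omega <= 1`
#' synonymous proposals are accepted with probability 1 and nonsynonymous
#' with probability `omega`, while for `omega > 1` synonymous proposals are
#' instead accepted with probability `1/omega`. Each lineage stops once its
#' realized synonymous substitutions per NG86 synonymous site reach
#' `target_ks / 2`, so the pairwise synonymous divergence is `target_ks`.
#'
#' @param ancestor Valid CDS string.
#' @param omega Target Ka/Ks (> 0).
#' @param target_ks Pairwise synonymous divergence (>= 0); 0 returns two
#'   copies of the ancestor.
#' @param pair_id,gene_a,gene_b Identifiers for the returned pair.
#' @return One-row `paralog_pairs` data frame; attribute `"events"` holds the
#'   realized synonymous/nonsynonymous substitution counts per lineage.
#' @export
evolve_pair <- function(ancestor, omega, target_ks, pair_id = "pair1",
                        gene_a = paste0(pair_id, "a"),
                        gene_b = paste0(pair_id, "b")) {
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (target_ks < 0) stop("target_ks must be >= 0", call. = FALSE)
  anc <- .validate_cds(ancestor, "ancestor")
  max_prop <- 50L * length(anc)
  la <- .evolve_lineage(anc, omega, target_ks / 2, max_prop)
  lb <- .evolve_lineage(anc, omega, target_ks / 2, max_prop)
  out <- data.frame(pair_id = pair_id, gene_a = gene_a, gene_b = gene_b,
                    cds_a = .int_to_seq(la$seq), cds_b = .int_to_seq(lb$seq),
                    stringsAsFactors = FALSE)
  class(out) <- c("paralog_pairs", "data.frame")
  attr(out, "events") <- data.frame(lineage = c("a", "b"),
                                    syn = c(la$syn, lb$syn),
                                    nonsyn = c(la$nonsyn, lb$nonsyn))
  attr(out, "omega") <- omega
  attr(out, "target_ks") <- target_ks
  out
}

.resolve_target_ks <- function(config) {
  tk <- config$target_ks
  if (length(tk) == config$n_pairs) tk
  else if (length(tk) == 1L) rep(tk, config$n_pairs)
  else if (length(tk) == 2L) stats::runif(config$n_pairs, tk[1L], tk[2L])
  else stop("target_ks must have length 1, 2 (range) or n_pairs", call. = FALSE)
}

.sample_grid <- function(config) {
  g <- expand.grid(replicate = seq_len(config$replicates),
                   time_index = seq_len(config$n_timepoints),
                   stress = config$stresses, stringsAsFactors = FALSE)
  g <- g[, c("stress", "time_index", "replicate")]
  treated <- data.frame(g, is_control = FALSE)
  ctrl <- unique(g[, c("stress", "time_index")])
  ctrl <- data.frame(ctrl, replicate = 1L, is_control = TRUE)
  meta <- rbind(treated, ctrl)
  meta$sample <- paste0(meta$stress, "_", meta$time_index, "_", meta$replicate,
                        ifelse(meta$is_control, "_ctrl", ""))
  meta[, c("sample", "stress", "time_index", "replicate", "is_control")]
}

#' Simulate an expression matrix for paralog pairs
#'
#' For each pair, the two genes' log-expression values across treated samples
#' are drawn from a bivariate normal with unit variances and correlation
#' `rho = exp(-lambda * Ks)`, plus independent measurement noise of standard
#' deviation `noise_sd`, then exponentiated to an FPKM-like scale. Control
#' samples are drawn independently at baseline.
#'
#' @param pairs `paralog_pairs` data frame.
#' @param ks_per_pair Numeric vector, one Ks per pair.
#' @param config `simulation_config` (supplies lambda, the sample grid and
#'   the baseline).
#' @return `expression_matrix` with `2 * nrow(pairs)` genes.
#' @export
simulate_expression <- function(pairs, ks_per_pair, config) {
  lambda <- config$coupling_lambda
  if (lambda < 0) stop("coupling_lambda must be >= 0", call. = FALSE)
  if (length(ks_per_pair) != nrow(pairs))
    stop("need one Ks per pair", call. = FALSE)
  meta <- .sample_grid(config)
  n_s <- nrow(meta)
  trt <- !meta$is_control
  mu <- config$baseline_log_mean
  genes <- as.vector(rbind(pairs$gene_a, pairs$gene_b))
  values <- matrix(NA_real_, nrow = length(genes), ncol = n_s,
                   dimnames = list(genes, meta$sample))
  for (i in seq_len(nrow(pairs))) {
    rho <- exp(-lambda * ks_per_pair[i])
    z1 <- stats::rnorm(n_s)
    z2 <- stats::rnorm(n_s)
    x <- z1
    y <- ifelse(trt, rho * z1 + sqrt(1 - rho^2) * z2, z2)
    x <- x + stats::rnorm(n_s, sd = config$noise_sd)
    y <- y + stats::rnorm(n_s, sd = config$noise_sd)
    values[2L * i - 1L, ] <- exp(mu + x)
    values[2L * i, ] <- exp(mu + y)
  }
  .new_expression_matrix(values, meta)
}

#' Simulate a differential-expression table
#'
#' Per gene and condition: with probability `de_fraction` the gene is DE
#' (`padj ~ U(0, 0.049)`, `|log2FC| = 1 + Exp(mean = effect_mu - 1)`, random
#' sign); otherwise `padj ~ U(0.05, 1)` and `|log2FC| ~ U(0, 1)`. Pairs
#' planted as "enhancing" follow neither-one-both DE over the three time
#' points of every stress; "decreasing" pairs follow the reverse.
#'
#' @param pairs `paralog_pairs` data frame.
#' @param config `simulation_config`.
#' @return DE data frame (`gene, stress, time_index, log2fc, padj,
#'   expressed`); attribute `"planted"` records each pair's planted
#'   trajectory label (`enhancing`, `decreasing` or `none`).
#' @export
simulate_de_table <- function(pairs, config) {
  if (config$de_fraction < 0 || config$de_fraction > 1)
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  n <- nrow(pairs)
  lab <- rep("none", n)
  n_enh <- round(config$enhancing_fraction * n)
  n_dec <- round(config$decreasing_fraction * n)
  if (n_enh + n_dec > 0) {
    pick <- sample.int(n, n_enh + n_dec)
    lab[pick[seq_len(n_enh)]] <- "enhancing"
    if (n_dec > 0) lab[pick[n_enh + seq_len(n_dec)]] <- "decreasing"
  }
  genes <- as.vector(rbind(pairs$gene_a, pairs$gene_b))
  grid <- expand.grid(time_index = seq_len(config$n_timepoints),
                      stress = config$stresses, stringsAsFactors = FALSE)
  draw_one <- function(is_de) {
    if (is_de) {
      lfc <- (1 + stats::rexp(1L, rate = 1 / (config$effect_mu - 1))) *
        sample(c(-1, 1), 1L)
      c(lfc, stats::runif(1L, 0, 0.049))
    } else {
      c(stats::runif(1L, 0, 1) * sample(c(-1, 1), 1L),
        stats::runif(1L, 0.05, 1))
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    rec <- vector("list", nrow(grid) * 2L)
    for (k in seq_len(nrow(grid))) {
      st <- grid$stress[k]; ti <- grid$time_index[k]
      if (lab[i] == "enhancing") {
        de_a <- ti >= 2L; de_b <- ti >= 3L
      } else if (lab[i] == "decreasing") {
        de_a <- ti <= 2L; de_b <- ti <= 1L
      } else {
        de_a <- stats::runif(1L) < config$de_fraction
        de_b <- stats::runif(1L) < config$de_fraction
      }
      da <- draw_one(de_a); db <- draw_one(de_b)
      rec[[2L * k - 1L]] <- data.frame(gene = ga, stress = st, time_index = ti,
                                       log2fc = da[1L], padj = da[2L],
                                       expressed = TRUE,
                                       stringsAsFactors = FALSE)
      rec[[2L * k]] <- data.frame(gene = gb, stress = st, time_index = ti,
                                  log2fc = db[1L], padj = db[2L],
                                  expressed = TRUE, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, rec)
  }
  de <- do.call(rbind, rows)
  rownames(de) <- NULL
  attr(de, "planted") <- data.frame(pair_id = pairs$pair_id, planted = lab,
                                    stringsAsFactors = FALSE)
  de
}

#' Simulate a complete paralog dataset
#'
#' Runs the full generator under one seed: ancestral sequences, pairwise
#' codon evolution at the configured omega and Ks, an expression matrix with
#' Ks-coupled within-pair correlation, a DE table, and a random TF subset.
#'
#' @param config `simulation_config`.
#' @return List of class `paralog_simulation`: `pairs`, `true_ks`,
#'   `expression`, `de`, `planted`, `tf_ids`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ks <- .resolve_target_ks(config)
  pair_ids <- sprintf("pair%04d", seq_len(config$n_pairs))
  pairs <- do.call(rbind, lapply(seq_len(config$n_pairs), function(i) {
    anc <- generate_ancestral_cds(config$codons_per_gene)
    p <- evolve_pair(anc, config$omega, ks[i], pair_id = pair_ids[i],
                     gene_a = sprintf("g%04da", i),
                     gene_b = sprintf("g%04db", i))
    attr(p, "events") <- NULL
    attr(p, "omega") <- NULL
    attr(p, "target_ks") <- NULL
    p
  }))
  rownames(pairs) <- NULL
  class(pairs) <- c("paralog_pairs", "data.frame")
  expr <- simulate_expression(pairs, ks, config)
  de <- simulate_de_table(pairs, config)
  planted <- attr(de, "planted")
  attr(de, "planted") <- NULL
  genes <- as.vector(rbind(pairs$gene_a, pairs$gene_b))
  n_tf <- round(config$tf_fraction * length(genes))
  tf_ids <- sort(sample(genes, n_tf))
  structure(list(pairs = pairs, true_ks = ks, expression = expr, de = de,
                 planted = planted, tf_ids = tf_ids, config = config),
            class = "paralog_simulation")
}

#' @export
print.paralog_simulation <- function(x, ...) {
  cat("Synthetic paralog dataset:", nrow(x$pairs), "pairs,",
      nrow(x$expression$values), "genes,",
      ncol(x$expression$values), "samples\n")
  cat(sprintf("  omega = %g, Ks in [%.3g, %.3g], lambda = %g, seed = %d\n",
              x$config$omega, min(x$true_ks), max(x$true_ks),
              x$config$coupling_lambda, x$config$seed))
  invisible(x)
}

#' Write all dataset files for a simulation
#'
#' @param sim `paralog_simulation`.
#' @param dir Output directory (created if missing).
#' @return Named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pairs = file.path(dir, "pairs.fasta"),
             expression = file.path(dir, "expression.tsv"),
             de = file.path(dir, "de.tsv"),
             tf = file.path(dir, "tf_list.txt"))
  write_pair_fasta(sim$pairs, paths[["pairs"]])
  write_expression_tsv(sim$expression, paths[["expression"]])
  write_de_tsv(sim$de, paths[["de"]])
  write_tf_list(sim$tf_ids, paths[["tf"]])
  invisible(paths)
}
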