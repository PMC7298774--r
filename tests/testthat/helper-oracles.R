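# Independent oracles used to cross-check the package implementation.
# They share no code with the package internals: translation goes through
# seqinr::translate and pathway enumeration is written as plain brute force.

oracle_translate_codon <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# brute-force NG86 site counting: enumerate all 9 single-nucleotide changes
# of every codon; a change is synonymous iff it preserves the amino acid and
# does not create a stop.
oracle_count_sites <- function(cds) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(cds, "")[[1]]
  codons <- vapply(seq_len(length(chars) / 3),
                   function(i) paste(chars[(3 * i - 2):(3 * i)], collapse = ""),
                   "")
  S <- 0
  for (codon in codons) {
    aa <- oracle_translate_codon(codon)
    for (pos in 1:3) {
      syn <- 0
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nt
        aa2 <- oracle_translate_codon(alt)
        if (aa2 != "*" && aa2 == aa) syn <- syn + 1
      }
      S <- S + syn / 3
    }
  }
  c(S = S, N = nchar(cds) - S)
}

# all permutations of a vector (n <= 3 here)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_perms(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

# brute-force pathway-averaged difference counting between two codons
oracle_codon_diff <- function(ca, cb) {
  d <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(d) == 0) return(c(0, 0))
  paths <- oracle_perms(d)
  res <- lapply(paths, function(ord) {
    cur <- ca
    sd <- nd <- 0
    blocked <- FALSE
    for (pos in ord) {
      aa1 <- oracle_translate_codon(cur)
      substr(cur, pos, pos) <- substr(cb, pos, pos)
      aa2 <- oracle_translate_codon(cur)
      if (aa2 == "*") blocked <- TRUE
      if (aa2 != "*" && aa2 == aa1) sd <- sd + 1 else nd <- nd + 1
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, TRUE, "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(mean(vapply(res[ok], `[[`, 0, "sd")), mean(vapply(res[ok], `[[`, 0, "nd")))
}

oracle_count_differences <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  sums <- rowSums(vapply(seq_along(ca),
                         function(i) oracle_codon_diff(ca[i], cb[i]),
                         numeric(2)))
  c(Sd = sums[1], Nd = sums[2])
}

# exhaustive Mann-Whitney two-sided p: enumerate all C(n, n1) labelings of
# the pooled sample, compute the U distribution, and take twice the smaller
# tail at the observed U (capped at 1).
oracle_mwu_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  lo <- mean(u_all <= u_obs + eps)
  hi <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(lo, hi))
}

# random sense-codon CDS built from the oracle side (seqinr codon table)
oracle_random_cds <- function(codons) {
  nts <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")
  sense <- all_codons[vapply(all_codons, oracle_translate_codon, "") != "*"]
  paste(sample(sense, codons, replace = TRUE), collapse = "")
}
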