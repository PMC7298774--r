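#' @title Nei-Gojobori (1986) Ka/Ks estimation
#' @description Count synonymous/nonsynonymous sites and differences per
#'   codon-aligned paralog pair, apply the Jukes-Cantor multiple-hit
#'   correction, and classify selection pressure from the Ka/Ks ratio.
#' @name ng86
NULL

.validate_cds <- function(cds, what = "CDS") {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds))
    stop(what, " must be a single character string", call. = FALSE)
  v <- .seq_to_int(cds)
  if (length(v) == 0L || length(v) %% 3L != 0L)
    stop(what, " length (", length(v), ") must be a positive multiple of 3",
         call. = FALSE)
  ids <- .codon_ids(v)
  if (any(.AA[ids] == "*"))
    stop(what, " contains a stop codon (codon ",
         which(.AA[ids] == "*")[1L], ")", call. = FALSE)
  v
}

#' Count synonymous and nonsynonymous sites of a coding sequence
#'
#' Each codon position contributes `f/3` synonymous sites, where `f` is the
#' number of the three possible single-nucleotide changes at that position
#' that preserve the amino acid; changes that create a stop codon count as
#' nonsynonymous. Site counts partition the sequence length: `S + N == L`.
#'
#' @param cds Nucleotide string (A/C/G/T), length divisible by 3, no stop
#'   codons.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' count_sites("TTT")  # S = 1/3: only TTC at the third position is synonymous
#' @export
count_sites <- function(cds) {
  v <- .validate_cds(cds)
  S <- sum(.SYN_FRAC[.codon_ids(v)])
  c(S = S, N = length(v) - S)
}

# permutations of substitution orders for codons differing at 1..3 positions
.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# pathway-averaged (Sd, Nd) between two sense codons given as triplets.
# Pathways passing through a stop codon are excluded unless every pathway is
# blocked, in which case all are included (stop steps counted nonsynonymous).
.codon_diff <- function(ta, tb) {
  d <- which(ta != tb)
  k <- length(d)
  if (k == 0L) return(c(0, 0))
  perms <- .PERMS[[k]]
  sd_all <- nd_all <- numeric(length(perms))
  valid <- logical(length(perms))
  for (i in seq_along(perms)) {
    ord <- d[perms[[i]]]
    cur <- ta
    sdi <- ndi <- 0
    ok <- TRUE
    for (pos in ord) {
      aa_from <- .AA[.triplet_to_codon_id(cur)]
      cur[pos] <- tb[pos]
      aa_to <- .AA[.triplet_to_codon_id(cur)]
      if (aa_to == "*") ok <- FALSE
      if (aa_to != "*" && aa_to == aa_from) sdi <- sdi + 1 else ndi <- ndi + 1
    }
    sd_all[i] <- sdi; nd_all[i] <- ndi; valid[i] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(perms))
  c(mean(sd_all[use]), mean(nd_all[use]))
}

#' Count synonymous and nonsynonymous differences between two aligned CDS
#'
#' Codons differing at one position are classed directly; codons differing at
#' k in 2..3 positions average the synonymous/nonsynonymous step counts over
#' all k! substitution orders, excluding pathways through stop codons (all
#' pathways are kept when every one is blocked). `Sd + Nd` equals the
#' pathway-averaged total number of differences.
#'
#' @param cds_a,cds_b Equal-length codon-aligned nucleotide strings.
#' @return Named numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' count_differences("GGG", "GGA")  # one synonymous third-position change
#' @export
count_differences <- function(cds_a, cds_b) {
  va <- .validate_cds(cds_a, "cds_a")
  vb <- .validate_cds(cds_b, "cds_b")
  if (length(va) != length(vb))
    stop("sequences have unequal lengths (", length(va), " vs ", length(vb), ")",
         call. = FALSE)
  ids_a <- .codon_ids(va)
  ids_b <- .codon_ids(vb)
  Sd <- Nd <- 0
  for (j in which(ids_a != ids_b)) {
    ta <- .codon_id_to_triplet(ids_a[j])
    tb <- .codon_id_to_triplet(ids_b[j])
    sn <- .codon_diff(ta, tb)
    Sd <- Sd + sn[1L]; Nd <- Nd + sn[2L]
  }
  c(Sd = Sd, Nd = Nd)
}

#' Jukes-Cantor distance correction
#'
#' Corrects a proportion of observed differences per site for multiple hits:
#' `d = -(3/4) * log(1 - (4/3) * p)`. Defined for `0 <= p < 0.75`; the
#' distance saturates (is undefined) at `p >= 0.75`.
#'
#' @param p Proportion of sites differing, in `[0, 0.75)`.
#' @return Corrected distance `d >= p`.
#' @export
jukes_cantor <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop("p must be a single number in [0, 0.75)", call. = FALSE)
  if (p >= 0.75)
    stop("saturation: Jukes-Cantor distance undefined for p >= 0.75 (p = ",
         format(p), ")", call. = FALSE)
  -0.75 * log(1 - (4 / 3) * p) + 0  # + 0 normalizes -0 at p = 0
}

# internal: JC that signals saturation with NA instead of an error
.jc_or_na <- function(p) {
  if (is.na(p) || p >= 0.75) NA_real_
  else -0.75 * log(1 - (4 / 3) * p) + 0
}

#' Ka, Ks and selection class for one paralog pair
#'
#' Nei-Gojobori estimation: site counts are averaged between the two
#' sequences, differences are pathway-averaged, and both proportions are
#' Jukes-Cantor corrected. `Ka/Ks > 1` is classed as positive selection,
#' `< 1` as negative (purifying) selection, and equality within `1e-9` as
#' neutral. The ratio is undefined (`NA`) when `Ks` is zero or saturated;
#' saturation yields `selection = "undefined"`, not an error.
#'
#' @param cds_a,cds_b Codon-aligned equal-length CDS strings, or `cds_a` may
#'   be a single-row paralog-pair data frame (as from [read_pair_fasta()]).
#' @param pair_id Identifier carried into the result.
#' @return One-row data frame with columns `pair_id, S, N, Sd, Nd, Ka, Ks,
#'   ka_ks, selection`.
#' @examples
#' compute_ka_ks("TTTAAAGGG", "TTTAAAGGA")
#' @export
compute_ka_ks <- function(cds_a, cds_b = NULL, pair_id = "pair") {
  if (is.data.frame(cds_a)) {
    stopifnot(nrow(cds_a) == 1L)
    pair_id <- as.character(cds_a$pair_id)
    cds_b <- cds_a$cds_b
    cds_a <- cds_a$cds_a
  }
  sa <- count_sites(cds_a)
  sb <- count_sites(cds_b)
  dd <- count_differences(cds_a, cds_b)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  Sd <- dd[["Sd"]]; Nd <- dd[["Nd"]]
  Ks <- if (S > 0) .jc_or_na(Sd / S) else NA_real_
  Ka <- if (N > 0) .jc_or_na(Nd / N) else NA_real_
  ka_ks <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  selection <- if (is.na(ka_ks)) "undefined"
    else if (abs(ka_ks - 1) <= 1e-9) "neutral"
    else if (ka_ks > 1) "positive" else "negative"
  out <- data.frame(pair_id = pair_id, S = S, N = N, Sd = Sd, Nd = Nd,
                    Ka = Ka, Ks = Ks, ka_ks = ka_ks, selection = selection,
                    stringsAsFactors = FALSE)
  class(out) <- c("kaks_estimates", "data.frame")
  out
}

#' Batch Ka/Ks over a table of paralog pairs
#'
#' @param pairs Paralog-pair data frame with columns `pair_id, cds_a, cds_b`
#'   (see [read_pair_fasta()]).
#' @return `kaks_estimates` data frame, one row per pair, in input order.
#' @export
kaks <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("pair_id", "cds_a", "cds_b") %in% names(pairs)))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    compute_ka_ks(pairs$cds_a[i], pairs$cds_b[i], pair_id = pairs$pair_id[i])
  }))
  rownames(out) <- NULL
  class(out) <- c("kaks_estimates", "data.frame")
  out
}

#' @export
print.kaks_estimates <- function(x, ...) {
  cat("Ka/Ks estimates (NG86 + Jukes-Cantor) for", nrow(x), "pair(s)\n")
  n_undef <- sum(is.na(x$ka_ks))
  if (n_undef > 0)
    cat("  ", n_undef, "pair(s) with undefined Ka/Ks (Ks zero or saturated)\n")
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.kaks_estimates <- function(object, ...) {
  def <- object[!is.na(object$ka_ks), , drop = FALSE]
  structure(list(
    n = nrow(object),
    n_defined = nrow(def),
    median_ka = stats::median(object$Ka, na.rm = TRUE),
    median_ks = stats::median(object$Ks, na.rm = TRUE),
    median_ka_ks = if (nrow(def)) stats::median(def$ka_ks) else NA_real_,
    selection = table(object$selection)
  ), class = "summary.kaks_estimates")
}

#' @export
print.summary.kaks_estimates <- function(x, ...) {
  cat("Pairs:", x$n, " (", x$n_defined, "with defined Ka/Ks )\n")
  cat(sprintf("Median Ka = %.4g, Ks = %.4g, Ka/Ks = %.4g\n",
              x$median_ka, x$median_ks, x$median_ka_ks))
  cat("Selection classes:\n")
  print(x$selection)
  invisible(x)
}
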