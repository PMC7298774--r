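# Standard genetic code and precomputed lookup tables used by the NG86
# estimator and the codon-evolution simulator.
#
# Internal nucleotide encoding: T=1, C=2, A=3, G=4 (the classical codon-table
# ordering); codon id = 16*(n1-1) + 4*(n2-1) + n3, in 1..64.

.NT <- c("T", "C", "A", "G")

.CODONS <- paste0(
  rep(.NT, each = 16L),
  rep(rep(.NT, each = 4L), times = 4L),
  rep(.NT, times = 16L)
)

# transl_table=1, codon order TTT, TTC, TTA, TTG, TCT, ...
.AA <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
                "")[[1]]
names(.AA) <- .CODONS

.STOP_IDS <- which(.AA == "*")

.codon_id_to_triplet <- function(id) {
  id <- id - 1L
  c(id %/% 16L, (id %/% 4L) %% 4L, id %% 4L) + 1L
}

.triplet_to_codon_id <- function(trip) {
  16L * (trip[1L] - 1L) + 4L * (trip[2L] - 1L) + trip[3L]
}

# nucleotide string <-> integer vector
.seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .NT)
  if (anyNA(v)) {
    bad <- strsplit(toupper(s), "", fixed = TRUE)[[1]][is.na(v)]
    stop("invalid nucleotide character(s): ", paste(unique(bad), collapse = ", "),
         " (only A/C/G/T accepted; ambiguity codes are rejected)", call. = FALSE)
  }
  v
}

.int_to_seq <- function(v) paste(.NT[v], collapse = "")

# codon ids for an integer-encoded sequence (length divisible by 3)
.codon_ids <- function(v) {
  n <- length(v) %/% 3L
  i1 <- v[seq(1L, by = 3L, length.out = n)]
  i2 <- v[seq(2L, by = 3L, length.out = n)]
  i3 <- v[seq(3L, by = 3L, length.out = n)]
  16L * (i1 - 1L) + 4L * (i2 - 1L) + i3
}

# syn change count per codon x position: of the 3 single-nucleotide changes at
# that position, how many preserve the amino acid (changes to stops count as
# nonsynonymous, i.e. are not counted). NA rows for stop codons.
.SYN_PER_POS <- local({
  m <- matrix(NA_real_, nrow = 64L, ncol = 3L)
  for (id in seq_len(64L)) {
    if (.AA[id] == "*") next
    trip <- .codon_id_to_triplet(id)
    for (pos in 1:3) {
      cnt <- 0L
      for (nt in 1:4) {
        if (nt == trip[pos]) next
        alt <- trip
        alt[pos] <- nt
        alt_id <- .triplet_to_codon_id(alt)
        if (.AA[alt_id] != "*" && .AA[alt_id] == .AA[id]) cnt <- cnt + 1L
      }
      m[id, pos] <- cnt
    }
  }
  m
})

# fractional synonymous sites per codon (NG86): sum over positions of syn/3
.SYN_FRAC <- rowSums(.SYN_PER_POS) / 3
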