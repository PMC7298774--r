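#' @title FF/FP/PP pattern classification
#' @description Classify paralog pairs per condition by their two genes'
#'   differential-expression calls (FF: both DE, FP: exactly one, PP:
#'   neither), group pairs into the seven stress-sharing clusters, call
#'   enhancing/decreasing trajectories over the three time points of each
#'   stress, and compute co-expressed fractions.
#' @name expression_patterns
NULL

.PATTERN_RANK <- c(PP = 0L, FP = 1L, FF = 2L)

#' Differential-expression call for one record
#'
#' A gene is called DE in a condition iff it is expressed, `padj < alpha`
#' and `|log2FC| > lfc` (strict inequalities, matching the edgeR-style
#' thresholds padj < 0.05 and |log2FC| > 1).
#'
#' @param record One-row DE data frame (or list) with `log2fc`, `padj`,
#'   `expressed`; `NULL` (a missing record) yields `FALSE`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @return Logical.
#' @export
call_de <- function(record, alpha = 0.05, lfc = 1) {
  if (is.null(record) || (is.data.frame(record) && nrow(record) == 0L))
    return(FALSE)
  isTRUE(as.logical(record$expressed)) &&
    is.finite(record$padj) && record$padj < alpha &&
    is.finite(record$log2fc) && abs(record$log2fc) > lfc
}

# vectorized DE calls for a whole DE table
.de_call_vec <- function(de, alpha, lfc) {
  de$expressed & !is.na(de$padj) & de$padj < alpha &
    is.finite(de$log2fc) & abs(de$log2fc) > lfc
}

#' Classify every pair in every condition as FF, FP or PP
#'
#' FF: both genes differentially expressed; FP: exactly one; PP: neither.
#' Genes with no DE record for a condition are treated as not DE.
#'
#' @param pairs `paralog_pairs` data frame.
#' @param de DE data frame (see [read_de_tsv()]).
#' @param alpha,lfc Thresholds passed to the DE call.
#' @param stresses,time_indices Conditions to classify (defaults: all
#'   present in `de`).
#' @return Data frame of class `pattern_calls` with columns
#'   `pair_id, stress, time_index, pattern`; one row per pair x condition.
#' @export
classify_pairs <- function(pairs, de, alpha = 0.05, lfc = 1,
                           stresses = NULL, time_indices = NULL) {
  if (is.null(stresses)) stresses <- unique(de$stress)
  if (is.null(time_indices)) time_indices <- sort(unique(de$time_index))
  if (nrow(de) > 0L) {
    key <- paste(de$gene, de$stress, de$time_index, sep = "\r")
    de_pass <- .de_call_vec(de, alpha, lfc)
    lut <- de_pass[!duplicated(key)]
    names(lut) <- key[!duplicated(key)]
  } else lut <- logical(0)
  is_de <- function(gene, st, ti) {
    v <- unname(lut[paste(gene, st, ti, sep = "\r")])
    !is.na(v) & v
  }
  grid <- expand.grid(time_index = time_indices, stress = stresses,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    st <- grid$stress[k]; ti <- grid$time_index[k]
    a <- is_de(pairs$gene_a, st, ti)
    b <- is_de(pairs$gene_b, st, ti)
    data.frame(pair_id = pairs$pair_id, stress = st, time_index = ti,
               pattern = ifelse(a & b, "FF", ifelse(a | b, "FP", "PP")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' Assign a stress-sharing cluster from a pair's per-stress membership
#'
#' The seven named clusters follow the Venn structure over the four
#' stresses: shared by all four; shared by the two abiotic stresses (Dr, Cd)
#' exactly; shared by the two biotic stresses (Bc, Pr) exactly; or specific
#' to a single stress. Venn regions not covered by those seven (e.g.
#' \{Dr, Bc\}) are assigned to `"other"` rather than dropped.
#'
#' @param membership Character vector of stresses where the pair shows the
#'   focal pattern; must be nonempty.
#' @return One of `all_four, abiotic_shared, biotic_shared, Dr_specific,
#'   Cd_specific, Bc_specific, Pr_specific, other`.
#' @export
assign_cluster <- function(membership) {
  membership <- unique(membership)
  if (length(membership) == 0L)
    stop("empty membership: pair has the focal pattern under no stress and ",
         "should not be clustered", call. = FALSE)
  if (!all(membership %in% .STRESSES))
    stop("unknown stress code(s): ",
         paste(setdiff(membership, .STRESSES), collapse = ", "), call. = FALSE)
  s <- sort(membership)
  if (length(s) == 4L) return("all_four")
  if (identical(s, sort(c("Dr", "Cd")))) return("abiotic_shared")
  if (identical(s, sort(c("Bc", "Pr")))) return("biotic_shared")
  if (length(s) == 1L) return(paste0(s, "_specific"))
  "other"
}

#' Cluster pairs with a focal pattern by stress sharing
#'
#' @param calls `pattern_calls` data frame.
#' @param focal Focal pattern type, `"FF"` or `"FP"`.
#' @param analysis_time Named integer vector mapping stress to the time index
#'   used for single-condition pattern calls (default: time point 3 for each
#'   stress, the last of the course).
#' @return Data frame `pair_id, cluster` for pairs showing the focal pattern
#'   under at least one stress.
#' @export
cluster_pairs <- function(calls, focal = c("FF", "FP"),
                          analysis_time = NULL) {
  focal <- match.arg(focal)
  stresses <- unique(calls$stress)
  if (is.null(analysis_time))
    analysis_time <- stats::setNames(rep(3L, length(stresses)), stresses)
  sub <- calls[calls$pattern == focal &
                 calls$time_index == analysis_time[calls$stress], ,
               drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(pair_id = character(), cluster = character(),
                      stringsAsFactors = FALSE))
  mem <- split(sub$stress, sub$pair_id)
  data.frame(pair_id = names(mem),
             cluster = vapply(mem, assign_cluster, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a three-point pattern trajectory
#'
#' Ranks encode the per-time-point pattern: PP = 0, FP = 1, FF = 2.
#' Enhancing means non-decreasing, ending at FF without starting there
#' (the PP -> FP -> FF progression); decreasing is the reverse; stable means
#' no change; anything else is mixed.
#'
#' @param ranks Integer vector of length 3, values in \{0, 1, 2\}, in time
#'   order.
#' @return One of `"enhancing"`, `"decreasing"`, `"stable"`, `"mixed"`.
#' @export
classify_trajectory <- function(ranks) {
  if (length(ranks) != 3L || !all(ranks %in% 0:2))
    stop("ranks must be three values in {0, 1, 2}", call. = FALSE)
  r1 <- ranks[1L]; r2 <- ranks[2L]; r3 <- ranks[3L]
  if (r1 == r2 && r2 == r3) return("stable")
  if (r1 <= r2 && r2 <= r3 && r3 == 2L && r1 < 2L) return("enhancing")
  if (r1 >= r2 && r2 >= r3 && r1 == 2L && r3 < 2L) return("decreasing")
  "mixed"
}

#' Trajectory calls for every pair and stress
#'
#' @param calls `pattern_calls` covering three time points per stress.
#' @return Data frame `pair_id, stress, r1, r2, r3, trajectory`.
#' @export
trajectory_calls <- function(calls) {
  stopifnot(inherits(calls, "data.frame"))
  rank <- .PATTERN_RANK[calls$pattern]
  key <- interaction(calls$pair_id, calls$stress, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), key), function(idx) {
    d <- calls[idx, , drop = FALSE]
    d <- d[order(d$time_index), , drop = FALSE]
    if (nrow(d) != 3L)
      stop("pair ", d$pair_id[1L], " stress ", d$stress[1L],
           ": expected 3 time points, got ", nrow(d), call. = FALSE)
    r <- .PATTERN_RANK[d$pattern]
    data.frame(pair_id = d$pair_id[1L], stress = d$stress[1L],
               r1 = r[1L], r2 = r[2L], r3 = r[3L],
               trajectory = classify_trajectory(unname(r)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pair_id, out$stress), , drop = FALSE]
}

#' Fraction of pairs co-expressed (within-pair Pearson r > 0.5)
#'
#' Computes each pair's Pearson correlation across treated samples (of one
#' stress, or all stresses) and reports the fraction exceeding the
#' co-expression threshold. Pairs with undefined correlation (zero variance)
#' are excluded from both numerator and denominator; their count is reported
#' in the `"n_undefined"` attribute.
#'
#' @param pairs `paralog_pairs`, or a subset of rows of one.
#' @param expr `expression_matrix`.
#' @param stress Single stress code, or `NULL` for all treated samples.
#' @param r_threshold Co-expression threshold on r (default 0.5, strict).
#' @return Fraction in `[0, 1]`.
#' @export
coexpressed_fraction <- function(pairs, expr, stress = NULL, r_threshold = 0.5) {
  if (nrow(pairs) == 0L) stop("empty pair subset", call. = FALSE)
  cors <- pair_correlations(pairs, expr, stress = stress)
  defined <- !is.na(cors$r)
  if (!any(defined)) stop("no pair has a defined correlation", call. = FALSE)
  out <- mean(cors$r[defined] > r_threshold)
  attr(out, "n_undefined") <- sum(!defined)
  out
}

#' Pattern counts per condition
#'
#' @param calls `pattern_calls`.
#' @return Data frame `stress, time_index, FF, FP, PP, n`; counts always sum
#'   to the number of pairs per condition.
#' @export
pattern_counts <- function(calls) {
  tab <- as.data.frame(table(stress = calls$stress,
                             time_index = calls$time_index,
                             pattern = factor(calls$pattern,
                                              levels = c("FF", "FP", "PP"))),
                       stringsAsFactors = FALSE)
  wide <- stats::reshape(tab, idvar = c("stress", "time_index"),
                         timevar = "pattern", direction = "wide")
  names(wide) <- sub("^Freq\\.", "", names(wide))
  wide$time_index <- as.integer(as.character(wide$time_index))
  wide$n <- wide$FF + wide$FP + wide$PP
  wide <- wide[wide$n > 0, , drop = FALSE]
  rownames(wide) <- NULL
  wide[order(wide$stress, wide$time_index), , drop = FALSE]
}
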