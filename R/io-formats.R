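#' @title File formats
#' @description Readers and writers for the external formats the pipeline
#'   consumes and produces: paired codon-aligned CDS FASTA, expression-matrix
#'   TSV, differential-expression TSV and plain-text transcription-factor
#'   lists. Every reader validates its input into the package's domain
#'   representation and fails with an error naming the offending record.
#' @name io_formats
NULL

.STRESSES <- c("Dr", "Cd", "Bc", "Pr")

.validate_pair_row <- function(pair_id, gene_a, gene_b, cds_a, cds_b) {
  if (gene_a == gene_b)
    stop("pair ", pair_id, ": gene_a and gene_b are identical (", gene_a, ")",
         call. = FALSE)
  for (g in c(a = cds_a, b = cds_b)) {
    tryCatch(.validate_cds(g),
             error = function(e) stop("pair ", pair_id, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (nchar(cds_a) != nchar(cds_b))
    stop("pair ", pair_id, ": unequal CDS lengths (", nchar(cds_a), " vs ",
         nchar(cds_b), "); input must be codon-aligned and gap-free",
         call. = FALSE)
  invisible(TRUE)
}

#' Read paralog pairs from FASTA
#'
#' Expects records grouped two per pair with headers `>pairID|geneID`. CDS
#' must be pre-aligned codon-wise: equal lengths, length divisible by 3,
#' A/C/G/T only (ambiguity codes rejected), and no stop codons anywhere in
#' the frame-0 translation — strip terminal stops before import.
#'
#' @param path FASTA file path.
#' @return Data frame of class `paralog_pairs` with columns
#'   `pair_id, gene_a, gene_b, cds_a, cds_b`, in file order.
#' @export
read_pair_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  n <- length(recs)
  if (n == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (n %% 2L != 0L)
    stop("odd record count (", n, ") in ", path,
         ": records must be grouped two per pair", call. = FALSE)
  headers <- names(recs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("header not of the form 'pairID|geneID': ",
         headers[which(lengths(parts) != 2L)[1L]], call. = FALSE)
  pid <- vapply(parts, `[`, "", 1L)
  gid <- vapply(parts, `[`, "", 2L)
  odd <- seq(1L, n, by = 2L)
  if (any(pid[odd] != pid[odd + 1L]))
    stop("consecutive records do not share a pair ID near record ",
         odd[which(pid[odd] != pid[odd + 1L])[1L]], call. = FALSE)
  out <- data.frame(
    pair_id = pid[odd],
    gene_a = gid[odd],
    gene_b = gid[odd + 1L],
    cds_a = toupper(vapply(recs[odd], as.character, "")),
    cds_b = toupper(vapply(recs[odd + 1L], as.character, "")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  for (i in seq_len(nrow(out)))
    .validate_pair_row(out$pair_id[i], out$gene_a[i], out$gene_b[i],
                       out$cds_a[i], out$cds_b[i])
  class(out) <- c("paralog_pairs", "data.frame")
  out
}

#' Write paralog pairs to FASTA
#'
#' @param pairs `paralog_pairs` data frame.
#' @param path Output path.
#' @export
write_pair_fasta <- function(pairs, path) {
  seqs <- as.list(as.vector(rbind(pairs$cds_a, pairs$cds_b)))
  nms <- as.vector(rbind(paste0(pairs$pair_id, "|", pairs$gene_a),
                         paste0(pairs$pair_id, "|", pairs$gene_b)))
  seqinr::write.fasta(seqs, names = nms, file.out = path, as.string = TRUE)
  invisible(path)
}

.parse_sample_names <- function(nms) {
  parts <- strsplit(nms, "_", fixed = TRUE)
  meta <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    is_ctrl <- length(p) == 4L && p[4L] == "ctrl"
    if (!(length(p) == 3L || is_ctrl))
      stop("sample name '", nms[i],
           "' not of the form stress_time_rep[_ctrl]", call. = FALSE)
    if (!p[1L] %in% .STRESSES)
      stop("unknown stress code '", p[1L], "' in sample '", nms[i],
           "' (expected one of ", paste(.STRESSES, collapse = "/"), ")",
           call. = FALSE)
    ti <- suppressWarnings(as.integer(p[2L]))
    rep <- suppressWarnings(as.integer(p[3L]))
    if (is.na(ti) || is.na(rep))
      stop("non-integer time or replicate index in sample '", nms[i], "'",
           call. = FALSE)
    data.frame(sample = nms[i], stress = p[1L], time_index = ti,
               replicate = rep, is_control = is_ctrl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, meta)
}

.new_expression_matrix <- function(values, sample_meta) {
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' Read an expression matrix from TSV
#'
#' First column is the gene ID; remaining column names encode sample metadata
#' as `stress_time_rep` for treated samples and `stress_time_rep_ctrl` for
#' controls, with stress one of Dr/Cd/Bc/Pr (e.g. `Dr_1_1`). Values are
#' FPKM-like: finite and nonnegative.
#'
#' @param path TSV path.
#' @return Object of class `expression_matrix`: a list with a numeric
#'   `values` matrix (genes x samples) and a `sample_meta` data frame
#'   (`sample, stress, time_index, replicate, is_control`).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >= 1 sample",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene ID: ", genes[duplicated(genes)][1L], call. = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (any(!is.finite(values)))
    stop("non-finite expression value for gene ",
         genes[which(!is.finite(values), arr.ind = TRUE)[1L, 1L]],
         call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value (", values[bad[1L], bad[2L]], ") for gene ",
         genes[bad[1L]], ", sample ", colnames(values)[bad[2L]], call. = FALSE)
  }
  meta <- .parse_sample_names(colnames(values))
  trt <- meta[!meta$is_control, , drop = FALSE]
  cond <- unique(meta[, c("stress", "time_index")])
  has_trt <- paste(trt$stress, trt$time_index) |> unique()
  missing <- setdiff(paste(cond$stress, cond$time_index), has_trt)
  if (length(missing))
    stop("condition(s) without any treated sample: ",
         paste(missing, collapse = ", "), call. = FALSE)
  .new_expression_matrix(values, meta)
}

#' Write an expression matrix to TSV
#'
#' Values are written at full double precision so a write/read round trip is
#' exact to numerical precision.
#'
#' @param expr `expression_matrix`.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  m <- expr$values
  df <- data.frame(gene = rownames(m),
                   matrix(sprintf("%.15g", m), nrow = nrow(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  stresses:", paste(sort(unique(x$sample_meta$stress)), collapse = ", "),
      "|", sum(!x$sample_meta$is_control), "treated,",
      sum(x$sample_meta$is_control), "control sample(s)\n")
  invisible(x)
}

#' Read a differential-expression table from TSV
#'
#' Columns: `gene, stress, time_index, log2FC, padj, expressed`. Missing
#' (gene, condition) combinations are treated downstream as not
#' differentially expressed.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene, stress, time_index, log2fc, padj,
#'   expressed`; empty (zero rows) for a header-only file.
#' @export
read_de_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("gene", "stress", "time_index", "log2fc", "padj", "expressed")
  if (!all(need %in% names(df)))
    stop("DE TSV must have columns gene, stress, time_index, log2FC, padj, ",
         "expressed", call. = FALSE)
  df <- df[, need]
  if (nrow(df) == 0L) return(df)
  df$expressed <- as.logical(df$expressed)
  bad_stress <- !df$stress %in% .STRESSES
  if (any(bad_stress))
    stop("unknown stress code '", df$stress[bad_stress][1L], "' for gene ",
         df$gene[bad_stress][1L], call. = FALSE)
  bad_p <- is.na(df$padj) | df$padj < 0 | df$padj > 1
  if (any(bad_p))
    stop("padj outside [0,1] (", df$padj[bad_p][1L], ") for gene ",
         df$gene[bad_p][1L], call. = FALSE)
  bad_fc <- df$expressed & !is.finite(df$log2fc)
  if (any(bad_fc))
    stop("non-finite log2FC for expressed gene ", df$gene[bad_fc][1L],
         call. = FALSE)
  df
}

#' Write a differential-expression table to TSV
#'
#' @param de DE data frame as returned by [read_de_tsv()].
#' @param path Output path.
#' @export
write_de_tsv <- function(de, path) {
  out <- de
  names(out)[names(out) == "log2fc"] <- "log2FC"
  out$log2FC <- sprintf("%.15g", out$log2FC)
  out$padj <- sprintf("%.15g", out$padj)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor gene list (one ID per line)
#'
#' @param path Text file path; blank lines ignored.
#' @return Character vector of unique TF gene IDs.
#' @export
read_tf_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicate TF gene ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  ids
}

#' Write a transcription-factor gene list
#' @param ids Character vector of gene IDs.
#' @param path Output path.
#' @export
write_tf_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

# result-table writer: 6 significant digits, NA encoded as "NA"
.write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         sprintf("%.6g", signif(out[[j]], 6)))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
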