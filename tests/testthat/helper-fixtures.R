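# Small programmatic fixtures shared across test files.

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

toy_pair_fasta <- function() {
  write_fasta_lines(c(">p1|gA", "TTTAAAGGG", ">p1|gB", "TTTAAAGGA"))
}

toy_pairs_df <- function(pair_id = "p1", gene_a = "gA", gene_b = "gB",
                         cds_a = "TTTAAAGGG", cds_b = "TTTAAAGGA") {
  out <- data.frame(pair_id = pair_id, gene_a = gene_a, gene_b = gene_b,
                    cds_a = cds_a, cds_b = cds_b, stringsAsFactors = FALSE)
  class(out) <- c("paralog_pairs", "data.frame")
  out
}

# expression_matrix built directly from a genes x samples value matrix with
# stress_time_rep[_ctrl] column names
toy_expression <- function(values) {
  meta <- paradiverge:::.parse_sample_names(colnames(values))
  paradiverge:::.new_expression_matrix(values, meta)
}

# DE table row(s) builder
de_rows <- function(gene, stress, time_index, log2fc, padj,
                    expressed = TRUE) {
  data.frame(gene = gene, stress = stress, time_index = time_index,
             log2fc = log2fc, padj = padj, expressed = expressed,
             stringsAsFactors = FALSE)
}
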