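# External file dialects. Counts: TSV, first column sample_id, remaining
# columns ASV ids. Taxonomy: TSV with asv_id, genus, label. Metadata: CSV with
# per-sample and per-pregnancy fields (days relative to delivery). Cytokines:
# CSV long form (sample_id, analyte, concentration, llod, ulod).

#' Read an ASV count table
#' @param path TSV with sample_id in the first column and one column per ASV.
#' @return Integer matrix, samples x ASVs, rownames = sample ids.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write an ASV count table
#' @param counts Samples x ASVs integer matrix.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a taxonomy table (TSV: asv_id, genus, label)
#' @param path Input path.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read sample metadata (CSV)
#' @param path Input path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cytokine panel (CSV long form)
#' @param path CSV with columns sample_id, analyte, concentration, llod, ulod.
#' @return data.frame.
#' @export
read_cytokines <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
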