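# Small fixture builders shared across tests.

toy_taxonomy <- function() {
  data.frame(
    asv_id = c("asvA", "asvB", "asvC", "asvD"),
    genus = c("Lactobacillus", "Lactobacillus", "Gardnerella", "Prevotella"),
    label = c("L. iners", "L. crispatus", "Gardnerella", "Prevotella"),
    stringsAsFactors = FALSE)
}

# count matrix from a list of named integer vectors
toy_counts <- function(rows) {
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  m
}

# random frequency vector of length k
random_freqs <- function(k) {
  x <- stats::rgamma(k, shape = stats::runif(1, 0.3, 3))
  x / sum(x)
}

# a tiny two-state cohort-like object for pipeline helpers
mini_cohort <- function(records_days, freqs_by_day, taxonomy = toy_taxonomy()) {
  # freqs_by_day: matrix of taxon frequencies per day (rows match days)
  counts <- round(freqs_by_day * 1e5)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("s%02d", seq_along(records_days))
  meta <- data.frame(sample_id = rownames(counts), pregnancy_id = "p1",
                     participant_id = "w1", day_vs_delivery = records_days,
                     stringsAsFactors = FALSE)
  list(counts = counts, taxonomy = taxonomy, sample_meta = meta)
}
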