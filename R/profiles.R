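# Sample tables are matrices with one row per sample (rownames = sample ids)
# and one column per ASV (colnames = ASV ids), integer counts. Sample
# metadata travels in a parallel data.frame keyed by sample_id. Days are
# relative to delivery: gestational days negative, delivery = day 0.

#' Remove low-yield samples
#'
#' Samples whose library size (row sum) falls below `min_reads` are dropped,
#' mirroring the sequencing QC rule of excluding swabs with library size
#' < 40,000 reads. Row order of the survivors is preserved.
#'
#' @param counts Integer matrix, samples x ASVs.
#' @param min_reads Minimum library size retained (default 40000; a sample
#'   with exactly `min_reads` reads is kept).
#' @param quiet Suppress the message reporting how many samples were removed.
#' @return The filtered count matrix. The number of removed samples is
#'   attached as attribute `"n_removed"`.
#' @export
filter_low_yield <- function(counts, min_reads = 40000, quiet = FALSE) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  keep <- rowSums(counts) >= min_reads
  out <- counts[keep, , drop = FALSE]
  if (!quiet) {
    message(sum(!keep), " of ", nrow(counts),
            " samples removed (library size < ", min_reads, ")")
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Convert counts to relative frequencies
#'
#' @param counts Non-negative count vector (or samples x ASVs matrix, which is
#'   normalised row-wise).
#' @return Frequencies summing to 1 (per row for matrices).
#' @export
relative_frequencies <- function(counts) {
  if (is.matrix(counts)) {
    ls <- rowSums(counts)
    if (any(ls == 0)) stop("empty sample (library size 0) in row(s): ",
                           paste(which(ls == 0), collapse = ", "))
    return(counts / ls)
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("empty sample: all counts are zero")
  counts / total
}

#' Shannon diversity and the effective number of ASVs
#'
#' Shannon index H = -sum f log f (natural log) over positive frequencies;
#' the effective number of ASVs is exp(H), the Hill number of order 1.
#'
#' @param frequencies Frequency vector summing to 1 (zeros allowed) or a
#'   samples x ASVs frequency matrix.
#' @return For a vector, a list with `shannon` and `effective_asvs`; for a
#'   matrix, a data.frame with one row per sample.
#' @export
diversity_metrics <- function(frequencies) {
  if (is.matrix(frequencies)) {
    if (any(frequencies < 0)) stop("negative frequency")
    h <- vegan::diversity(frequencies, index = "shannon")
    return(data.frame(sample_id = rownames(frequencies),
                      shannon = unname(h),
                      effective_asvs = unname(exp(h)),
                      stringsAsFactors = FALSE))
  }
  if (any(frequencies < 0)) stop("negative frequency")
  h <- vegan::diversity(rbind(frequencies), index = "shannon")[[1]]
  list(shannon = h, effective_asvs = exp(h))
}

#' Most abundant (top) ASV
#'
#' Ties are broken by the lexicographically smallest ASV id so the result is
#' deterministic.
#'
#' @param frequencies Named frequency vector.
#' @return List with `asv_id` and `frequency`.
#' @export
top_asv <- function(frequencies) {
  if (length(frequencies) == 0) stop("empty frequency vector")
  if (is.null(names(frequencies))) stop("frequencies must be named by ASV id")
  m <- max(frequencies)
  cand <- sort(names(frequencies)[frequencies == m])
  list(asv_id = cand[[1]], frequency = unname(m))
}

#' Designate the community state of one sample
#'
#' A sample is labelled "diverse" when its Shannon diversity index exceeds
#' `diverse_sdi` or its top-ASV frequency falls below `diverse_topfreq`;
#' otherwise it takes the taxonomic label of its top ASV. Flags record
#' majority (> 0.5), super-majority (> 2/3) and dominance (> 0.7) status of
#' the top ASV.
#'
#' @param frequencies Named frequency vector for one QC-passing sample.
#' @param taxonomy data.frame with columns `asv_id` and `label` mapping every
#'   ASV to its display label (species for curated species, otherwise genus).
#' @param diverse_sdi Shannon threshold above which the sample is diverse.
#' @param diverse_topfreq Top-ASV frequency below which the sample is diverse.
#'   Set to 0 to use the diversity rule alone.
#' @param supermajority Super-majority cutoff (default 2/3).
#' @return List with `label`, `top_asv_id`, `top_asv_frequency`, `shannon`,
#'   `is_majority`, `is_supermajority`, `is_dominated`.
#' @export
designate_state <- function(frequencies, taxonomy, diverse_sdi = 2,
                            diverse_topfreq = 0.5, supermajority = 2 / 3) {
  ta <- top_asv(frequencies)
  div <- diversity_metrics(frequencies)
  if (div$shannon > diverse_sdi || ta$frequency < diverse_topfreq) {
    label <- "diverse"
  } else {
    hit <- match(ta$asv_id, taxonomy$asv_id)
    if (is.na(hit)) stop("ASV missing from taxonomy: ", ta$asv_id)
    label <- taxonomy$label[[hit]]
  }
  list(label = label,
       top_asv_id = ta$asv_id,
       top_asv_frequency = ta$frequency,
       shannon = div$shannon,
       is_majority = ta$frequency > 0.5,
       is_supermajority = ta$frequency > supermajority,
       is_dominated = ta$frequency > 0.7)
}

#' Designate community states for a whole count table
#'
#' @param counts Integer matrix, samples x ASVs.
#' @param taxonomy As in [designate_state()].
#' @inheritParams designate_state
#' @return data.frame with one row per sample: `sample_id`, `label`,
#'   `top_asv_id`, `top_asv_frequency`, `shannon`, `effective_asvs`, and the
#'   three status flags.
#' @export
designate_states <- function(counts, taxonomy, diverse_sdi = 2,
                             diverse_topfreq = 0.5, supermajority = 2 / 3) {
  freq <- relative_frequencies(counts)
  rows <- lapply(seq_len(nrow(freq)), function(i) {
    st <- designate_state(freq[i, ], taxonomy, diverse_sdi, diverse_topfreq,
                          supermajority)
    data.frame(sample_id = rownames(freq)[i],
               label = st$label, top_asv_id = st$top_asv_id,
               top_asv_frequency = st$top_asv_frequency,
               shannon = st$shannon, effective_asvs = exp(st$shannon),
               is_majority = st$is_majority,
               is_supermajority = st$is_supermajority,
               is_dominated = st$is_dominated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample frequency of a taxon (summing member ASVs)
#'
#' @param freq Frequency matrix, samples x ASVs.
#' @param taxonomy data.frame with `asv_id` and `label`.
#' @param taxon Display label whose member-ASV frequencies are summed. ASVs
#'   with `genus == taxon` are also matched when a `genus` column is present,
#'   so genus-level taxa (e.g. "Lactobacillus") aggregate across species.
#' @return Numeric vector, one value per sample.
#' @export
taxon_frequency <- function(freq, taxonomy, taxon) {
  member <- taxonomy$asv_id[taxonomy$label == taxon]
  if (!is.null(taxonomy$genus)) {
    member <- union(member, taxonomy$asv_id[taxonomy$genus == taxon])
  }
  member <- intersect(colnames(freq), member)
  if (length(member) == 0) return(rep(0, nrow(freq)))
  rowSums(freq[, member, drop = FALSE])
}

#' Average gestational frequency of a taxon within one pregnancy
#'
#' The unweighted mean, over gestational samples only (day_vs_delivery < 0),
#' of the per-sample summed frequency of all ASVs mapped to `taxon`. A
#' pregnancy is called predominant for the taxon when this mean exceeds 0.5.
#'
#' @param counts Count matrix for the pregnancy's samples.
#' @param days Integer vector of day_vs_delivery, parallel to rows of counts.
#' @param taxonomy,taxon As in [taxon_frequency()].
#' @param predominance_cutoff Mean frequency above which the pregnancy is
#'   flagged predominant (default 0.5, strict).
#' @return List with `mean_frequency` and `predominant`.
#' @export
average_gestational_frequency <- function(counts, days, taxonomy, taxon,
                                          predominance_cutoff = 0.5) {
  stopifnot(nrow(counts) == length(days))
  gest <- days < 0
  if (!any(gest)) stop("no gestational samples (day_vs_delivery < 0)")
  freq <- relative_frequencies(counts[gest, , drop = FALSE])
  m <- mean(taxon_frequency(freq, taxonomy, taxon))
  list(mean_frequency = m, predominant = m > predominance_cutoff)
}

#' Pairwise dissimilarity between two samples
#'
#' Bray-Curtis (optionally on fourth-root transformed counts, which moderates
#' the influence of extremely dominant ASVs) or Canberra, scaled by the
#' number of non-double-zero coordinates so both metrics live in \[0, 1\].
#'
#' @param a,b Count vectors over the same ASV key set (names compared when
#'   present).
#' @param metric "bray_curtis" or "canberra".
#' @param transform "none" or "fourth_root".
#' @return A dissimilarity in \[0, 1\].
#' @export
dissimilarity <- function(a, b, metric = c("bray_curtis", "canberra"),
                          transform = c("none", "fourth_root")) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  if (length(a) != length(b)) stop("mismatched ASV key sets")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("mismatched ASV key sets")
  if (all(a == 0) && all(b == 0)) stop("both samples are all-zero")
  x <- rbind(a, b)
  if (transform == "fourth_root") x <- x^0.25
  method <- c(bray_curtis = "bray", canberra = "canberra")[[metric]]
  as.numeric(vegan::vegdist(x, method = method))
}
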