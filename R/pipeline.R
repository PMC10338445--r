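# High-level drivers that run the standard analysis steps on a cohort object
# (simulated or assembled from files with the read_* helpers).

#' QC-filter a cohort and designate per-sample community states
#'
#' @param cohort List with `counts`, `taxonomy`, `sample_meta` (as produced
#'   by [simulate_cohort()]).
#' @param min_reads Low-yield threshold passed to [filter_low_yield()].
#' @param diverse_sdi,diverse_topfreq State-designation thresholds.
#' @return data.frame: sample metadata joined with the state table of
#'   [designate_states()] for QC-passing samples.
#' @export
cohort_states <- function(cohort, min_reads = 40000, diverse_sdi = 2,
                          diverse_topfreq = 0.5) {
  counts <- filter_low_yield(cohort$counts, min_reads, quiet = TRUE)
  st <- designate_states(counts, cohort$taxonomy, diverse_sdi, diverse_topfreq)
  meta <- cohort$sample_meta[match(st$sample_id, cohort$sample_meta$sample_id), ]
  cbind(meta, st[, setdiff(names(st), "sample_id")], row.names = NULL)
}

#' Taxa variables for network and ordination analyses
#'
#' Agglomerates ASV frequencies to the genus level, except the genus
#' Lactobacillus, which is kept at species level, and appends the Shannon
#' diversity index as an additional variable.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param taxonomy data.frame with `asv_id`, `genus`, `label`.
#' @param include_sdi Append an `SDI` column (default TRUE).
#' @return Numeric matrix, samples x (genera + Lactobacillus species
#'   \[+ SDI\]).
#' @export
taxa_variables <- function(counts, taxonomy, include_sdi = TRUE) {
  freq <- relative_frequencies(counts)
  group <- ifelse(taxonomy$genus == "Lactobacillus", taxonomy$label,
                  taxonomy$genus)[match(colnames(freq), taxonomy$asv_id)]
  agg <- vapply(unique(group), function(g) {
    rowSums(freq[, group == g, drop = FALSE])
  }, numeric(nrow(freq)))
  if (include_sdi) {
    agg <- cbind(agg, SDI = vegan::diversity(freq, index = "shannon"))
  }
  agg
}

#' Postpartum time-to-dominance analysis for one taxon
#'
#' QC-filters the cohort, extracts per-pregnancy dominance records, and fits
#' the Kaplan-Meier curve.
#'
#' @inheritParams cohort_states
#' @param taxon Focal taxon (species label or genus, e.g. "Lactobacillus").
#' @param threshold Dominance threshold (default 0.7).
#' @param horizon_days Horizon for the cumulative incidence (default 365).
#' @return List: `records`, `km` ([km_fit()]), `incidence`
#'   ([cumulative_incidence_at()]).
#' @export
cohort_time_to_dominance <- function(cohort, taxon = "Lactobacillus",
                                     threshold = 0.7, horizon_days = 365,
                                     min_reads = 40000) {
  counts <- filter_low_yield(cohort$counts, min_reads, quiet = TRUE)
  meta <- cohort$sample_meta[cohort$sample_meta$sample_id %in% rownames(counts), ]
  records <- cohort_dominance_records(counts, meta, cohort$taxonomy, taxon,
                                      threshold)
  km <- km_fit(records)
  list(records = records,
       km = km,
       incidence = cumulative_incidence_at(km, horizon_days))
}

#' Parity association for one focal state on gestational samples
#'
#' @inheritParams cohort_states
#' @param focal_state Focal community state (default "L. crispatus").
#' @param seed RNG seed for the subsampling.
#' @param n_per_gestation,n_iterations Passed to [subsample_aggregate()].
#' @return A [subsample_aggregate()] result.
#' @export
cohort_parity <- function(cohort, focal_state = "L. crispatus", seed,
                          n_per_gestation = 6, n_iterations = 100,
                          min_reads = 40000) {
  st <- cohort_states(cohort, min_reads)
  gest <- st[st$phase == "gestation", ]
  exposure <- stats::setNames(
    as.numeric(cohort$pregnancy_meta$prior_live_birth),
    cohort$pregnancy_meta$pregnancy_id)
  subsample_aggregate(gest$label, gest$pregnancy_id, exposure, focal_state,
                      n_per_gestation, n_iterations, seed)
}
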