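# Species-level labelling of ASVs by alignment to type-strain 16S references.
# Alignment is semi-global: the (short) query must align end to end, while
# end-gaps in the (full-length) reference are free, so a 235-nt V4 amplicon
# scores against the homologous window of a ~1.5 kb reference.

#' Curated multi-species label groups
#'
#' Multi-species assignments wholly contained in one of these groups are
#' shortened to the single species known to dominate the human vaginal
#' microbiota.
#' @format Named list of character vectors.
#' @export
lactobacillus_curation <- list(
  "L. crispatus" = c("L. crispatus", "L. acidophilus", "L. gallinarum"),
  "L. gasseri"   = c("L. gasseri", "L. hominis", "L. johnsonii",
                     "L. taiwanensis"),
  "L. jensenii"  = c("L. jensenii", "L. fornicalis")
)

.iupac_submat <- function() {
  letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m)[1:4] <- 1  # only unambiguous identical bases count as matches
  m
}

#' Pairwise identity of a query against one reference
#'
#' Semi-global alignment (free end-gaps in the reference only; match +1,
#' mismatch -1, gap -2; ambiguity codes count as mismatches). Identity is the
#' number of matching columns divided by the number of query-spanning
#' alignment columns.
#'
#' @param query,reference Uppercase IUPAC DNA strings.
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(query, reference) {
  if (nchar(query) == 0 || nchar(reference) == 0) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global-local",
    substitutionMatrix = .iupac_submat(),
    gapOpening = 0, gapExtension = 2)
  columns <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / columns
}

#' Assign a query ASV to reference species
#'
#' Identity is computed against every reference; if the maximum reaches
#' `threshold` the query is assigned to all species attaining it (ties give
#' multi-species assignments), otherwise it is left unassigned.
#'
#' @param query DNA string.
#' @param db Named character vector of reference sequences (names = species).
#' @param threshold Minimum accepted identity (default 0.98).
#' @return List with `species_set` (sorted), `best_identity`, `assigned`.
#' @export
assign_species <- function(query, db, threshold = 0.98) {
  if (length(db) == 0) stop("empty reference database")
  ids <- vapply(db, function(ref) pairwise_identity(query, ref), numeric(1))
  best <- max(ids)
  assigned <- best >= threshold
  species <- if (assigned) sort(names(db)[ids >= best - 1e-12]) else character(0)
  list(species_set = species, best_identity = best, assigned = assigned)
}

#' Standardize a (possibly multi-species) assignment to a display label
#'
#' If the species set is wholly contained in one curated group the group's
#' short label is returned; otherwise the sorted species are joined with "/".
#'
#' @param species_set Character vector of species names.
#' @param curation_map Named list of groups (default
#'   [lactobacillus_curation]).
#' @return Display label.
#' @export
standardize_label <- function(species_set, curation_map = lactobacillus_curation) {
  if (length(species_set) == 0) stop("empty species set")
  for (short in names(curation_map)) {
    if (all(species_set %in% curation_map[[short]])) return(short)
  }
  paste(sort(species_set), collapse = "/")
}

#' Assign species labels to a FASTA of ASV sequences
#'
#' @param query_fasta Path to a FASTA of ASV sequences (headers = ASV ids).
#' @param reference_fasta Path to a FASTA of type-strain 16S sequences
#'   (headers = species names).
#' @param threshold Minimum accepted identity.
#' @return data.frame: asv_id, label, identity, assigned.
#' @export
assign_species_table <- function(query_fasta, reference_fasta, threshold = 0.98) {
  queries <- Biostrings::readDNAStringSet(query_fasta)
  refs <- Biostrings::readDNAStringSet(reference_fasta)
  db <- as.character(refs)
  names(db) <- names(refs)
  rows <- lapply(seq_along(queries), function(i) {
    a <- assign_species(as.character(queries[[i]]), db, threshold)
    data.frame(asv_id = names(queries)[i],
               label = if (a$assigned) standardize_label(a$species_set) else NA_character_,
               identity = a$best_identity, assigned = a$assigned,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
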