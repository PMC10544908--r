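#' Pairwise alignment identity against a reference
#'
#' Global alignment with free end gaps (match +1, mismatch -1, gap open 2,
#' gap extend 1). Identity is matches divided by the number of alignment
#' columns spanned by both sequences: end-gap columns are excluded, internal
#' gap columns count against identity. `aln_length` is that column count —
#' the BLAST hit-length analogue.
#'
#' @param query Character vector of query sequences.
#' @param reference A single reference sequence.
#' @return A tibble with one row per query: `identity`, `aln_length`, `score`.
#' @export
align_identity <- function(query, reference) {
  if (any(nchar(query) == 0) || nchar(reference) == 0) {
    abort("empty sequence in alignment")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query), Biostrings::DNAString(reference),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 2, gapExtension = 1)
  aln_len <- Biostrings::nchar(pa)
  tibble::tibble(identity = Biostrings::nmatch(pa) / aln_len,
                 aln_length = as.integer(aln_len),
                 score = Biostrings::score(pa))
}

# Identity of each query against each reference of one region.
# Returns a long tibble: query_index, ref_id, species, identity, aln_length,
# score. All references are scanned (reference sets here are small).
identity_scan <- function(queries, db, region) {
  refs <- db[db$region == region, , drop = FALSE]
  if (nrow(refs) == 0) abort(sprintf("no references for region %s", region))
  purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    hit <- align_identity(queries, refs$seq_ungapped[i])
    hit$query_index <- seq_along(queries)
    hit$ref_id <- refs$id[i]
    hit$species <- refs$species[i]
    hit
  })
}

#' Best reference hit per query
#'
#' Scans every reference of the region and keeps the best hit, ranked by
#' alignment score (the BLAST-like criterion: ranking by identity alone
#' would let a spurious short perfect end-overlap against an unrelated
#' reference outrank a genuine full-length hit). Ties on score are broken
#' by higher identity, then longer `aln_length`, then lexicographic
#' `ref_id`. A tie between references at the top score and identity is
#' recorded (`tie`, `tie_species`), so classification can flag
#' cross-parental-type ties.
#'
#' @param query Character vector of query sequences.
#' @param db A [ref_db()] reference database.
#' @param region Region whose references to scan.
#' @return A tibble with one row per query: `ref_id`, `species`, `identity`,
#'   `aln_length`, `score`, `tie` (logical), `tie_species`
#'   (comma-joined species at the tied optimum).
#' @export
best_hit <- function(query, db, region) {
  scan <- identity_scan(query, db, region)
  scan |>
    group_by(.data$query_index) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
            dplyr::desc(.data$aln_length), .data$ref_id, .by_group = TRUE) |>
    summarise(
      # tie fields first: summarise() evaluates sequentially and the
      # scalar columns below shadow the per-reference vectors
      tie = sum(.data$score == .data$score[1] &
                  .data$identity == .data$identity[1]) > 1,
      tie_species = paste(sort(unique(
        .data$species[.data$score == .data$score[1] &
                        .data$identity == .data$identity[1]])),
        collapse = ","),
      ref_id = .data$ref_id[1], species = .data$species[1],
      identity = .data$identity[1], aln_length = .data$aln_length[1],
      score = .data$score[1],
      .groups = "drop") |>
    select("query_index", "ref_id", "species", "identity", "aln_length",
           "score", "tie", "tie_species") |>
    arrange(.data$query_index) |>
    select(-"query_index")
}
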