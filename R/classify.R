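#' Assign ribotypes to parental types
#'
#' Each ribotype gets its best reference hit ([best_hit()]). It is assigned
#' the parental type of the hit species iff the alignment spans more than
#' `min_len` columns AND the identity strictly exceeds the region's
#' threshold AND the top identity is not tied between references of
#' different parental types. Otherwise it is `TOO_SHORT` (length test
#' failed) or `AMBIGUOUS`; both are excluded from downstream proportions.
#' Ties between references of the same parental type are assigned normally:
#' the type, not the species, is the unit of inference.
#'
#' @param table A `ribotype_tbl` from [dereplicate()].
#' @param db A [ref_db()].
#' @param thresholds A `threshold_set` from [derive_identity_thresholds()]
#'   (the row matching the table's region is used), or a single numeric
#'   identity threshold.
#' @param grouping Named character vector mapping species labels to parental
#'   type labels, e.g. `c(Lm = "Lolium-type", Fp = "Festuca-type")`. Every
#'   species present in the database must be mapped.
#' @param min_len Minimum alignment length, exclusive (default 200).
#' @return A tibble of class `classified_tbl`: the input rows plus
#'   per-ribotype `assignment`, `species`, `identity`, `aln_length`,
#'   `tie_species` columns. The grouping is attached as attribute
#'   `"grouping"`.
#' @export
classify_ribotypes <- function(table, db, thresholds, grouping,
                               min_len = 200) {
  check_df_cols(table, c("ribotype_id", "seq", "sample_id", "count"), "table")
  region <- unique(table$region) %||% abort("table lacks a region column")
  if (length(region) != 1) abort("classify_ribotypes() expects one region")

  db_species <- unique(db$species[db$region == region])
  unmapped <- setdiff(db_species, names(grouping))
  if (length(unmapped) > 0) {
    abort(sprintf("grouping is missing species present in the database: %s",
                  paste(unmapped, collapse = ", ")))
  }
  if (is.numeric(thresholds)) {
    thr <- thresholds
  } else {
    check_df_cols(thresholds, c("region", "identity_threshold"), "thresholds")
    thr <- thresholds$identity_threshold[thresholds$region == region]
    if (length(thr) != 1) {
      abort(sprintf("thresholds has no row for region %s", region))
    }
  }

  ribo <- distinct(table, .data$ribotype_id, .data$seq)
  hits <- best_hit(ribo$seq, db, region)
  hits$ribotype_id <- ribo$ribotype_id

  type_of <- function(sp) unname(grouping[sp])
  cross_tie <- hits$tie & vapply(strsplit(hits$tie_species, ","), function(sp) {
    n_distinct(type_of(sp)) > 1
  }, logical(1))
  assignment <- dplyr::case_when(
    hits$aln_length <= min_len ~ "TOO_SHORT",
    hits$identity <= thr ~ "AMBIGUOUS",
    cross_tie ~ "AMBIGUOUS",
    TRUE ~ type_of(hits$species))

  out <- table |>
    left_join(tibble::tibble(ribotype_id = hits$ribotype_id,
                             assignment = assignment,
                             species = hits$species,
                             identity = hits$identity,
                             aln_length = hits$aln_length,
                             tie_species = ifelse(hits$tie, hits$tie_species,
                                                  NA_character_)),
              by = "ribotype_id")
  attr(out, "grouping") <- grouping
  attr(out, "identity_threshold") <- thr
  class(out) <- c("classified_tbl", class(out))
  out
}

#' Remove global singletons
#'
#' Drops every ribotype whose total count across all samples of the dataset
#' equals one. Singletons mostly represent polymerase error or other PCR
#' artefacts; removal happens after classification, and proportions are
#' computed from the counts that remain.
#'
#' @param table A `classified_tbl` or `ribotype_tbl` (long counts).
#' @return The table without global singletons, same class and attributes.
#' @export
remove_global_singletons <- function(table) {
  check_df_cols(table, c("ribotype_id", "count"), "table")
  if (nrow(table) == 0) return(table)
  totals <- tapply(table$count, table$ribotype_id, sum)
  keep <- names(totals)[totals > 1]
  out <- table[table$ribotype_id %in% keep, , drop = FALSE]
  for (a in c("grouping", "identity_threshold")) {
    attr(out, a) <- attr(table, a)
  }
  out
}

#' Per-sample classification accounting
#'
#' Read-level counts of assigned / ambiguous / too-short sequences per
#' sample, for audit reports.
#'
#' @param classified A `classified_tbl`.
#' @return A tibble with one row per sample and per outcome.
#' @export
classification_summary <- function(classified) {
  check_df_cols(classified, c("sample_id", "assignment", "count"), "classified")
  classified |>
    mutate(outcome = dplyr::case_when(
      .data$assignment %in% c("AMBIGUOUS", "TOO_SHORT") ~ .data$assignment,
      TRUE ~ "assigned")) |>
    group_by(.data$sample_id, .data$outcome) |>
    summarise(n_reads = sum(.data$count), n_ribotypes = n(), .groups = "drop")
}
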