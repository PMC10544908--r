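#' Per-sample parental-type proportions
#'
#' For each sample, the fraction of classified sequences (not ribotypes —
#' counts are sequence-weighted) assigned to each parental type.
#' `AMBIGUOUS` and `TOO_SHORT` ribotypes are excluded from the denominator
#' but their read counts are reported so the exclusion is auditable.
#' Third-party types (e.g. Lolium-type reads in a Festuca x Festuca cross)
#' appear as their own category.
#'
#' @param classified A `classified_tbl`, singletons already removed.
#' @param samples Optional sample sheet; its metadata columns (genotype,
#'   cross, generation, template, region) are joined by `sample_id`.
#' @param sample_id Optional single sample to restrict to.
#' @return A tibble of class `proportion_tbl`, one row per sample x parental
#'   type: `sample_id`, metadata, `region`, `parental_type`, `n_type`, `p`,
#'   `n_classified`, `n_ambiguous`, `flag` (`"no_classified_reads"` when the
#'   denominator is zero, in which case `p` is `NA`).
#' @export
sample_proportions <- function(classified, samples = NULL, sample_id = NULL) {
  check_df_cols(classified, c("sample_id", "assignment", "count"), "classified")
  if (!is.null(sample_id)) {
    classified <- classified[classified$sample_id %in% sample_id, ,
                             drop = FALSE]
  }
  grouping <- attr(classified, "grouping")
  types <- sort(unique(c(unname(grouping),
                         setdiff(classified$assignment,
                                 c("AMBIGUOUS", "TOO_SHORT")))))
  region <- if ("region" %in% names(classified)) {
    distinct(classified, .data$sample_id, .data$region)
  } else {
    NULL
  }

  per_sample <- classified |>
    group_by(.data$sample_id) |>
    summarise(
      n_classified = sum(.data$count[!(.data$assignment %in%
                                         c("AMBIGUOUS", "TOO_SHORT"))]),
      n_ambiguous = sum(.data$count[.data$assignment %in%
                                      c("AMBIGUOUS", "TOO_SHORT")]),
      .groups = "drop")

  by_type <- classified |>
    filter(!(.data$assignment %in% c("AMBIGUOUS", "TOO_SHORT"))) |>
    group_by(.data$sample_id, parental_type = .data$assignment) |>
    summarise(n_type = sum(.data$count), .groups = "drop")

  out <- tidyr::expand_grid(sample_id = per_sample$sample_id,
                            parental_type = types) |>
    left_join(by_type, by = c("sample_id", "parental_type")) |>
    mutate(n_type = dplyr::coalesce(.data$n_type, 0L)) |>
    left_join(per_sample, by = "sample_id") |>
    mutate(p = ifelse(.data$n_classified > 0,
                      .data$n_type / .data$n_classified, NA_real_),
           flag = ifelse(.data$n_classified > 0, NA_character_,
                         "no_classified_reads"))
  if (!is.null(region)) out <- left_join(out, region, by = "sample_id")
  if (!is.null(samples)) {
    meta_cols <- intersect(c("sample_id", "genotype", "cross", "generation",
                             "template"), names(samples))
    out <- left_join(out, distinct(samples[meta_cols]), by = "sample_id")
  }
  class(out) <- c("proportion_tbl", class(out))
  out
}

#' Aggregate proportions over biological replicates
#'
#' Mean and sample standard deviation (n - 1) of each parental type's
#' fraction across genotypes (the biological replicates), per group.
#' Groups with a single genotype get `sd_p = 0` and are flagged.
#'
#' @param records A `proportion_tbl` from [sample_proportions()].
#' @param by Grouping columns (default cross, generation, template, region).
#' @return A tibble of class `dominance_summary`: group key, `parental_type`,
#'   `mean_p`, `sd_p`, `n_genotypes`, `flag`.
#' @export
aggregate_proportions <- function(records,
                                  by = c("cross", "generation", "template",
                                         "region")) {
  check_df_cols(records, c(by, "parental_type", "p"), "records")
  out <- records |>
    filter(!is.na(.data$p)) |>
    group_by(dplyr::across(dplyr::all_of(c(by, "parental_type")))) |>
    summarise(mean_p = mean(.data$p),
              sd_p = ifelse(n() > 1, sd(.data$p), 0),
              n_genotypes = n(), .groups = "drop") |>
    mutate(flag = ifelse(.data$n_genotypes == 1, "single_replicate",
                         NA_character_))
  class(out) <- c("dominance_summary", class(out))
  out
}

#' Nucleolar-dominance report
#'
#' For every (cross, generation, region) with both templates present:
#' DNA and cDNA mean proportions per parental type, the dominant type
#' (argmax of the cDNA means), the dominance strength (max cDNA mean), the
#' DNA-to-cDNA shift per type, and a dominance label: `"dominant"` when the
#' strength reaches `dominance_threshold` (near-total silencing of the other
#' parent), `"partial_dominance"` at `codominance_threshold`, else
#' `"codominant"`; exact cDNA ties are labelled `"tie"`.
#'
#' @param summaries A `dominance_summary` from [aggregate_proportions()].
#' @param dominance_threshold cDNA mean declaring full dominance (0.99).
#' @param codominance_threshold Lower bound for partial dominance (0.60).
#' @return A tibble of class `dominance_report`, one row per group x type,
#'   with per-group `dominant_type`, `strength` and `label` repeated on each
#'   row; `shift` = cDNA mean - DNA mean for the type.
#' @export
dominance_report <- function(summaries, dominance_threshold = 0.99,
                             codominance_threshold = 0.60) {
  check_df_cols(summaries, c("cross", "generation", "template", "region",
                             "parental_type", "mean_p"), "summaries")
  wide <- summaries |>
    select("cross", "generation", "region", "template", "parental_type",
           "mean_p", "sd_p") |>
    tidyr::pivot_wider(names_from = "template",
                       values_from = c("mean_p", "sd_p"))
  for (col in c("mean_p_DNA", "mean_p_cDNA", "sd_p_DNA", "sd_p_cDNA")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- wide |>
    filter(is.na(.data$mean_p_DNA) | is.na(.data$mean_p_cDNA)) |>
    distinct(.data$cross, .data$generation, .data$region)
  if (nrow(incomplete) > 0) {
    warn(sprintf("omitting %d group(s) lacking a DNA or cDNA summary",
                 nrow(incomplete)))
    wide <- dplyr::anti_join(wide, incomplete,
                             by = c("cross", "generation", "region"))
  }
  if (nrow(wide) == 0) {
    out <- wide |>
      mutate(strength = numeric(0), dominant_type = character(0),
             shift = numeric(0), label = character(0))
    class(out) <- c("dominance_report", class(out))
    return(out)
  }
  out <- wide |>
    group_by(.data$cross, .data$generation, .data$region) |>
    mutate(
      strength = max(.data$mean_p_cDNA),
      is_tie = sum(.data$mean_p_cDNA == max(.data$mean_p_cDNA)) > 1,
      dominant_type = ifelse(.data$is_tie, "tie",
                             .data$parental_type[which.max(.data$mean_p_cDNA)]),
      shift = .data$mean_p_cDNA - .data$mean_p_DNA,
      label = dplyr::case_when(
        .data$is_tie ~ "tie",
        .data$strength >= dominance_threshold ~ "dominant",
        .data$strength >= codominance_threshold ~ "partial_dominance",
        TRUE ~ "codominant")) |>
    ungroup() |>
    select(-"is_tie")
  class(out) <- c("dominance_report", class(out))
  out
}
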