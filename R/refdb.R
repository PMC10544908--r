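IUPAC_OK <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-", ".")

#' Construct a parental ITS reference database
#'
#' A reference database is a tibble of species-labelled, region-labelled
#' aligned ITS sequences. Within one (region) alignment all sequences must
#' have equal aligned length; `seq_ungapped` is derived by dropping gaps.
#'
#' @param refs A data frame with columns `id`, `species`, `region`,
#'   `seq_aligned`.
#' @return A tibble of class `ref_db` with an added `seq_ungapped` column.
#' @export
ref_db <- function(refs) {
  check_df_cols(refs, c("id", "species", "region", "seq_aligned"), "refs")
  refs <- tibble::as_tibble(refs)
  refs$seq_aligned <- toupper(refs$seq_aligned)
  bad_chars <- stringr::str_remove_all(refs$seq_aligned,
                                       "[-.ACGTURYSWKMBDHVN]")
  bad <- which(nchar(bad_chars) > 0)
  if (length(bad) > 0) {
    abort(sprintf("reference '%s' contains non-IUPAC character(s): %s",
                  refs$id[bad[1]], substr(bad_chars[bad[1]], 1, 5)))
  }
  if (!all(refs$region %in% REGIONS)) {
    abort("reference region must be ITS1, ITS2 or FULL_ITS")
  }
  widths <- tapply(nchar(refs$seq_aligned), refs$region, function(w) length(unique(w)))
  if (any(widths > 1)) {
    abort("all aligned sequences of one region must have equal length")
  }
  if (anyDuplicated(paste(refs$id, refs$region))) {
    abort("duplicated reference (id, region)")
  }
  refs$seq_ungapped <- stringr::str_remove_all(refs$seq_aligned, "[-.]")
  class(refs) <- c("ref_db", class(refs))
  refs
}

#' Load a reference database from FASTA plus metadata
#'
#' Every FASTA record id must appear in the metadata table, which supplies
#' the species label and region. Records labelled `FULL_ITS` are additionally
#' sliced into ITS1/ITS2 sub-references when 1-based inclusive alignment
#' coordinates (`its1_start`..`its2_end`) are present in the metadata.
#'
#' @param fasta_path Path to an aligned reference FASTA.
#' @param metadata_path Path to a TSV with columns `id`, `species`, `region`
#'   and optional `its1_start`, `its1_end`, `its2_start`, `its2_end`.
#' @return A `ref_db` tibble.
#' @export
load_references <- function(fasta_path, metadata_path) {
  fa <- read_fasta(fasta_path)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  check_df_cols(meta, c("id", "species", "region"), "reference metadata")
  missing <- setdiff(fa$id, meta$id)
  if (length(missing) > 0) {
    abort(sprintf("FASTA record '%s' has no metadata row", missing[1]))
  }
  refs <- inner_join(fa, meta, by = "id")
  refs$seq_aligned <- toupper(refs$seq)

  full <- refs[refs$region == "FULL_ITS", , drop = FALSE]
  out <- refs[refs$region != "FULL_ITS",
              c("id", "species", "region", "seq_aligned")]
  if (nrow(full) > 0) {
    coord_cols <- c("its1_start", "its1_end", "its2_start", "its2_end")
    if (!all(coord_cols %in% names(meta))) {
      abort("FULL_ITS records require its1/its2 slice coordinates in metadata")
    }
    sliced <- purrr::map_dfr(seq_len(nrow(full)), function(i) {
      r <- full[i, ]
      tibble::tibble(
        id = r$id, species = r$species, region = c("ITS1", "ITS2"),
        seq_aligned = c(substr(r$seq_aligned, r$its1_start, r$its1_end),
                        substr(r$seq_aligned, r$its2_start, r$its2_end)))
    })
    out <- bind_rows(out, sliced)
  }
  ref_db(out)
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("<ref_db> %d reference(s), %d species, regions: %s\n",
              nrow(x), n_distinct(x$species),
              paste(sort(unique(x$region)), collapse = ", ")))
  NextMethod()
}
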