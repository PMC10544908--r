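#' Merge paired-end reads by best ungapped overlap
#'
#' For each pair, the reverse mate is reverse-complemented and the overlap
#' with the forward mate that maximises the match count is found (ties go
#' to the longer overlap). Consensus at a disagreeing overlap column keeps
#' the base with the higher Phred quality when the difference is at least
#' `delta_q`, else writes `N`; at agreeing columns the higher quality is
#' kept. Pairs with no overlap of at least `min_overlap` columns, or whose
#' best overlap has a mismatch fraction above `max_mismatch_frac`, are
#' rejected with a reason code.
#'
#' @param pairs Tibble with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (Phred+33).
#' @param min_overlap Minimum acceptable overlap length (columns).
#' @param max_mismatch_frac Maximum mismatch fraction in the best overlap.
#' @param delta_q Minimum Phred difference for a base to win a disagreement.
#' @return A tibble with one row per input pair: `id`, `seq`, `qual`,
#'   `overlap_len`, `n_mismatch`, `merged` (logical), `reason` (NA when
#'   merged).
#' @export
merge_read_pairs <- function(pairs, min_overlap = 20, max_mismatch_frac = 0.25,
                             delta_q = 6) {
  check_df_cols(pairs, c("id", "r1_seq", "r1_qual", "r2_seq", "r2_qual"),
                "pairs")
  if (any(nchar(pairs$r1_seq) == 0 | nchar(pairs$r2_seq) == 0)) {
    abort("empty mate sequence")
  }
  if (any(nchar(pairs$r1_seq) != nchar(pairs$r1_qual)) ||
      any(nchar(pairs$r2_seq) != nchar(pairs$r2_qual))) {
    abort("sequence/quality length mismatch in read pairs")
  }
  res <- .overlap_merge_cpp(pairs$r1_seq, pairs$r1_qual,
                            revcomp(pairs$r2_seq), str_rev(pairs$r2_qual),
                            as.integer(min_overlap), max_mismatch_frac,
                            as.integer(delta_q))
  tibble::tibble(id = pairs$id, seq = res$seq, qual = res$qual,
                 overlap_len = res$overlap_len, n_mismatch = res$n_mismatch,
                 merged = res$merged, reason = res$reason)
}

#' Demultiplex contigs on dual 12-nt barcodes
#'
#' A contig is assigned to a sample iff its 5' 12-mer matches the sample's
#' forward barcode and the reverse complement of its 3' 12-mer matches the
#' reverse barcode, both within `max_bc_mismatch` substitutions, for exactly
#' one sample. Contigs matching no sample are `unassigned`; contigs matching
#' two or more are routed to `ambiguous` and never double-counted.
#'
#' @param contigs Tibble with columns `id`, `seq` (merged contigs).
#' @param sheet A validated sample sheet (one region's rows).
#' @param max_bc_mismatch Per-barcode substitution tolerance (default 0).
#' @param barcode_len Barcode length (12 per the library design).
#' @return The contig tibble with added `sample_id` (NA when not assigned)
#'   and `demux_status` (`assigned`/`unassigned`/`ambiguous`) columns.
#' @export
demultiplex <- function(contigs, sheet, max_bc_mismatch = 0, barcode_len = 12L) {
  check_df_cols(contigs, c("id", "seq"), "contigs")
  sheet <- validate_sample_sheet(sheet)
  n <- nrow(contigs)
  len <- nchar(contigs$seq)
  bc5 <- substr(contigs$seq, 1L, barcode_len)
  bc3 <- revcomp(substring(contigs$seq, len - barcode_len + 1L, len))

  n_hits <- integer(n)
  hit <- rep(NA_character_, n)
  for (i in seq_len(nrow(sheet))) {
    ok <- hamming_at(bc5, sheet$fwd_barcode[i]) <= max_bc_mismatch &
      hamming_at(bc3, sheet$rev_barcode[i]) <= max_bc_mismatch &
      len >= 2L * barcode_len
    n_hits <- n_hits + ok
    hit[ok & n_hits == 1L] <- sheet$sample_id[i]
  }
  status <- dplyr::case_when(n_hits == 1L ~ "assigned",
                             n_hits == 0L ~ "unassigned",
                             TRUE ~ "ambiguous")
  contigs |>
    mutate(sample_id = ifelse(status == "assigned", hit, NA_character_),
           demux_status = status)
}

#' Trim barcodes and primers off demultiplexed contigs
#'
#' Strips the 12-nt barcode plus forward primer at the 5' end and the
#' reverse complement of the reverse primer plus barcode at the 3' end.
#' Primers are located by a Hamming match of at most `max_primer_mismatch`
#' at their expected offsets. Contigs failing the forward-primer search are
#' retried reverse-complemented before rejection.
#'
#' @param contigs Tibble with columns `id`, `seq`.
#' @param fwd_primer,rev_primer Primer sequences (as ordered, 5'->3').
#' @param max_primer_mismatch Hamming tolerance per primer (default 2).
#' @param barcode_len Barcode length (12).
#' @return The tibble with added `insert`, `trimmed` (logical) and
#'   `trim_reason` columns.
#' @export
trim_barcodes_and_primers <- function(contigs, fwd_primer, rev_primer,
                                      max_primer_mismatch = 2,
                                      barcode_len = 12L) {
  check_df_cols(contigs, c("id", "seq"), "contigs")
  npf <- nchar(fwd_primer)
  npr <- nchar(rev_primer)
  rp_rc <- revcomp(rev_primer)

  try_orientation <- function(seqs) {
    len <- nchar(seqs)
    fwd_ok <- hamming_at(seqs, fwd_primer, offset = barcode_len + 1L) <=
      max_primer_mismatch
    rev_off <- len - barcode_len - npr + 1L
    rev_ok <- rev_off >= barcode_len + npf + 1L &
      hamming_at(seqs, rp_rc, offset = pmax(rev_off, 1L)) <= max_primer_mismatch
    insert <- substr(seqs, barcode_len + npf + 1L, pmax(rev_off - 1L, 0L))
    list(fwd_ok = fwd_ok & len >= 2L * barcode_len + npf + npr,
         rev_ok = rev_ok, insert = insert)
  }

  fw <- try_orientation(contigs$seq)
  rcv <- try_orientation(revcomp(contigs$seq))
  use_rc <- !fw$fwd_ok & rcv$fwd_ok
  fwd_ok <- ifelse(use_rc, rcv$fwd_ok, fw$fwd_ok)
  rev_ok <- ifelse(use_rc, rcv$rev_ok, fw$rev_ok)
  insert <- ifelse(use_rc, rcv$insert, fw$insert)

  trimmed <- fwd_ok & rev_ok
  reason <- dplyr::case_when(trimmed ~ NA_character_,
                             !fwd_ok ~ "fwd_primer_not_found",
                             TRUE ~ "rev_primer_not_found")
  contigs |>
    mutate(insert = ifelse(trimmed, insert, NA_character_),
           trimmed = trimmed, trim_reason = reason)
}

#' Screen inserts against the reference database
#'
#' Keeps an insert iff its best identity to any reference of the region is
#' at least `min_identity` over an alignment covering at least `min_cov` of
#' the insert. This removes contaminant (e.g. endophyte) and otherwise
#' unspecific sequences; 50/50 parental chimeras pass (they match both
#' parents well above the floor) and are dealt with at classification.
#' Identical insert strings are aligned once internally.
#'
#' @param inserts Tibble with an `insert` column (e.g. trimmed contigs).
#' @param db A [ref_db()].
#' @param region Region of the inserts.
#' @param min_identity Identity floor (default 0.75).
#' @param min_cov Minimum alignment columns / insert length (default 0.5).
#' @return The tibble with added `filter_identity`, `kept` (logical) and
#'   `filter_reason` columns.
#' @export
reference_filter <- function(inserts, db, region, min_identity = 0.75,
                             min_cov = 0.5) {
  check_df_cols(inserts, "insert", "inserts")
  check_region(region)
  n <- nrow(inserts)
  empty <- is.na(inserts$insert) | nchar(inserts$insert) == 0
  uniq <- unique(inserts$insert[!empty])
  if (length(uniq) > 0) {
    hits <- best_hit(uniq, db, region)
    idx <- match(inserts$insert, uniq)
    ident <- hits$identity[idx]
    cov <- hits$aln_length[idx] / nchar(inserts$insert)
  } else {
    ident <- rep(NA_real_, n)
    cov <- rep(NA_real_, n)
  }
  keep <- !empty & ident >= min_identity & cov >= min_cov
  keep[is.na(keep)] <- FALSE
  reason <- dplyr::case_when(
    keep ~ NA_character_,
    empty ~ "empty_insert",
    ident < min_identity ~ "low_identity",
    TRUE ~ "low_coverage")
  inserts |>
    mutate(filter_identity = ident, kept = keep, filter_reason = reason)
}

#' Dereplicate inserts into a ribotype count table
#'
#' Exact-string dereplication across the entire dataset (DNA and cDNA
#' samples of one region pooled): each distinct insert string becomes one
#' ribotype; per-sample counts are preserved. Ribotype ids are assigned by
#' decreasing total abundance (ties broken by sequence) so they are
#' deterministic for a given input multiset.
#'
#' @param inserts Tibble with columns `sample_id`, `insert` (one row per
#'   retained read) and optionally `region`.
#' @return A tibble of class `ribotype_tbl`, long format: `ribotype_id`,
#'   `seq`, `sample_id`, `count` (plus `region` if supplied).
#' @export
dereplicate <- function(inserts) {
  check_df_cols(inserts, c("sample_id", "insert"), "inserts")
  region <- if ("region" %in% names(inserts)) unique(inserts$region) else NULL
  if (length(region) > 1) abort("dereplicate() expects one region at a time")

  counts <- inserts |>
    count(.data$sample_id, seq = .data$insert, name = "count")
  ids <- counts |>
    group_by(.data$seq) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$total), .data$seq) |>
    mutate(ribotype_id = sprintf("rt%06d", row_number()))
  out <- counts |>
    left_join(select(ids, "seq", "ribotype_id"), by = "seq") |>
    select("ribotype_id", "seq", "sample_id", "count") |>
    arrange(.data$ribotype_id, .data$sample_id)
  if (!is.null(region)) out$region <- region
  class(out) <- c("ribotype_tbl", class(out))
  out
}
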