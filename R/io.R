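#' Read a FASTQ file into a tibble
#'
#' Phred+33 qualities; gzip input is handled transparently. Records whose
#' sequence and quality lengths disagree raise an error naming the record.
#'
#' @param path Path to a FASTQ (optionally .gz) file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # structural prepass: Biostrings cannot report which record is broken,
  # so check the 4-line framing and per-record lengths first
  con <- gzfile(path, open = "rt")
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ '%s': truncated record at line %d",
                  path, 4L * (length(lines) %/% 4) + 1L))
  }
  if (length(lines) > 0) {
    ids <- lines[seq(1, length(lines), by = 4)]
    seq_len_ <- nchar(lines[seq(2, length(lines), by = 4)])
    qual_len <- nchar(lines[seq(4, length(lines), by = 4)])
    bad <- which(seq_len_ != qual_len)
    if (length(bad) > 0) {
      abort(sprintf(
        "FASTQ record %d ('%s', line %d): sequence and quality lengths differ",
        bad[1], sub("^@", "", ids[bad[1]]), 4L * (bad[1] - 1L) + 1L))
    }
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(id = as.character(names(x)),
                 seq = unname(as.character(x)),
                 qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write a tibble of reads to FASTQ
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_df_cols(reads, c("id", "seq", "qual"), "reads")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0) {
    abort(sprintf("FASTQ record %d ('%s'): sequence and quality lengths differ",
                  bad[1], reads$id[bad[1]]))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA (optionally .gz) file.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = as.character(names(x)), seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_df_cols(seqs, c("id", "seq"), "seqs")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id)), path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet describes one amplicon library per row: sample identity,
#' biological metadata (genotype, cross, generation), the template the
#' amplicon was made from (DNA or cDNA), the ITS region, and the 12-nt
#' forward/reverse barcodes plus primer sequences used for that sample.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A validated tibble (see [validate_sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  check_df_cols(sheet, c("sample_id", "genotype", "cross", "generation",
                         "template", "region", "fwd_barcode", "rev_barcode",
                         "fwd_primer", "rev_primer"), "sample sheet")
  if (anyDuplicated(sheet$sample_id)) {
    abort("sample sheet: duplicated sample_id")
  }
  if (!all(sheet$template %in% c("DNA", "cDNA"))) {
    abort("sample sheet: template must be 'DNA' or 'cDNA'")
  }
  if (!all(sheet$region %in% c("ITS1", "ITS2"))) {
    abort("sample sheet: region must be 'ITS1' or 'ITS2'")
  }
  if (!all(nchar(sheet$fwd_barcode) == 12L) ||
      !all(nchar(sheet$rev_barcode) == 12L)) {
    abort("sample sheet: barcodes must be exactly 12 nt")
  }
  key <- paste(sheet$fwd_barcode, sheet$rev_barcode, sheet$region)
  if (anyDuplicated(key)) {
    abort("sample sheet: (fwd_barcode, rev_barcode, region) must be unique")
  }
  tibble::as_tibble(sheet)
}

# TSV writer that prefixes a commented provenance header.
write_tsv_stamped <- function(df, path, stamp) {
  writeLines(paste0("# ", stamp), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_stamped <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
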