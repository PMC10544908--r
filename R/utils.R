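DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors; IUPAC
#' ambiguity codes are handled (via Biostrings).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse each string (used for quality strings alongside revcomp).
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Vectorised Hamming distance between equal-length strings x and a single
# pattern placed at 1-based `offset` within x. Positions beyond nchar(x)
# count as mismatches.
hamming_at <- function(x, pattern, offset = 1L) {
  np <- nchar(pattern)
  mm <- integer(length(x))
  for (k in seq_len(np)) {
    pos <- offset + k - 1L
    mm <- mm + (substr(x, pos, pos) != substr(pattern, k, k))
  }
  mm
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

check_df_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

REGIONS <- c("ITS1", "ITS2", "FULL_ITS")

check_region <- function(region) {
  if (!is.character(region) || length(region) != 1 || !(region %in% REGIONS)) {
    abort(sprintf("`region` must be one of %s", paste(REGIONS, collapse = ", ")))
  }
  region
}
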