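#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing sites between two aligned sequences, over the
#' alignment columns where both sequences carry an unambiguous base.
#' Gaps (`-`, `.`) and ambiguity codes (including `N`) are treated as
#' missing and the column is skipped (pairwise deletion). Returns `NA`
#' (the undefined marker) when no column is comparable.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return A fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
pairwise_p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("aligned sequences must have equal length")
  }
  ra <- charToRaw(toupper(a))
  rb <- charToRaw(toupper(b))
  ok <- ra %in% charToRaw("ACGT") & rb %in% charToRaw("ACGT")
  n_comp <- sum(ok)
  if (n_comp == 0) return(NA_real_)
  sum(ra[ok] != rb[ok]) / n_comp
}

#' Between-group mean p-distance
#'
#' Mean pairwise p-distance over all cross-group sequence pairs, for every
#' pair of species groups in the reference database (the within-group mean
#' is reported on the diagonal rows but is not used for thresholds).
#' Pairs with undefined distance are excluded from the mean and counted.
#'
#' @param db A [ref_db()] reference database.
#' @param region Which region alignment to use (`"ITS1"` or `"ITS2"`).
#' @return A tibble of class `divergence_tbl` with columns `region`,
#'   `group1`, `group2`, `distance`, `n_pairs`, `n_undefined`.
#' @export
between_group_mean_distance <- function(db, region) {
  check_region(region)
  refs <- db[db$region == region, , drop = FALSE]
  if (nrow(refs) == 0) abort(sprintf("no references for region %s", region))
  groups <- sort(unique(refs$species))
  seqs <- split(refs$seq_aligned, refs$species)
  if (any(vapply(seqs, length, 1L) < 1)) abort("empty species group")

  pair_mean <- function(sa, sb, within = FALSE) {
    d <- c()
    if (within) {
      n <- length(sa)
      if (n < 2) return(list(distance = NA_real_, n_pairs = 0L, n_undef = 0L))
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- c(d, pairwise_p_distance(sa[i], sa[j]))
      }
    } else {
      for (x in sa) for (y in sb) d <- c(d, pairwise_p_distance(x, y))
    }
    list(distance = if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE),
         n_pairs = length(d), n_undef = sum(is.na(d)))
  }

  grid <- expand.grid(i = seq_along(groups), j = seq_along(groups))
  grid <- grid[grid$i <= grid$j, ]
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    g1 <- groups[grid$i[k]]; g2 <- groups[grid$j[k]]
    pm <- pair_mean(seqs[[g1]], seqs[[g2]], within = g1 == g2)
    tibble::tibble(region = region, group1 = g1, group2 = g2,
                   distance = pm$distance, n_pairs = pm$n_pairs,
                   n_undefined = pm$n_undef)
  })
  class(out) <- c("divergence_tbl", class(out))
  out
}

#' Derive region-specific classification identity thresholds
#'
#' The identity threshold for a region is set just above the identity that
#' the two most similar species could produce: take the minimum finite
#' between-group distance, compute `1 - min`, and round UP to the nearest
#' multiple of `margin_step` (exact multiples are left unchanged).
#' Downstream classification compares identity to the threshold strictly
#' (identity must exceed it).
#'
#' @param div A `divergence_tbl` from [between_group_mean_distance()]
#'   (may hold several regions).
#' @param margin_step Rounding grid for the threshold, default 0.005
#'   (half a percentage point).
#' @return A tibble of class `threshold_set` with one row per region:
#'   `region`, `min_cross_divergence`, `identity_threshold`, `rule_id`,
#'   `margin_step`.
#' @export
derive_identity_thresholds <- function(div, margin_step = 0.005) {
  check_df_cols(div, c("region", "group1", "group2", "distance"), "div")
  cross <- div[div$group1 != div$group2, , drop = FALSE]
  out <- purrr::map_dfr(unique(cross$region), function(rg) {
    d <- cross$distance[cross$region == rg]
    d <- d[is.finite(d)]
    if (length(d) == 0) {
      abort(sprintf("region %s: all between-group distances are undefined", rg))
    }
    mind <- min(d)
    thr <- ceiling((1 - mind) / margin_step - 1e-9) * margin_step
    tibble::tibble(region = rg, min_cross_divergence = mind,
                   identity_threshold = thr,
                   rule_id = "ceil(1-min_divergence, step)",
                   margin_step = margin_step)
  })
  class(out) <- c("threshold_set", class(out))
  out
}
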