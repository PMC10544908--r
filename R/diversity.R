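#' Choose the common subsampling depth
#'
#' The depth equals the second-lowest per-sample total in the dataset, so
#' that all but (at most) the single shallowest sample can be compared at
#' equal depth; samples with fewer sequences than the chosen depth are
#' excluded and listed.
#'
#' @param totals Named numeric vector of per-sample totals, or a data frame
#'   with columns `sample_id`, `total`.
#' @param rule Only `"second_lowest"` is implemented.
#' @return A list of class `subsample_depth`: `m`, `excluded` (sample ids or
#'   indices), `rule`.
#' @export
choose_subsample_depth <- function(totals, rule = "second_lowest") {
  if (is.data.frame(totals)) {
    check_df_cols(totals, c("sample_id", "total"), "totals")
    totals <- setNames(totals$total, totals$sample_id)
  }
  if (length(totals) < 2) {
    abort("need at least 2 samples to choose a subsampling depth")
  }
  if (rule != "second_lowest") abort("unknown depth rule")
  m <- sort(totals)[2]
  nm <- names(totals) %||% as.character(seq_along(totals))
  structure(list(m = as.integer(unname(m)), excluded = nm[totals < m],
                 rule = rule),
            class = "subsample_depth")
}

#' @export
print.subsample_depth <- function(x, ...) {
  cat(sprintf("<subsample_depth> m = %d (rule: %s); %d sample(s) excluded%s\n",
              x$m, x$rule, length(x$excluded),
              if (length(x$excluded)) paste0(": ", paste(x$excluded, collapse = ", ")) else ""))
  invisible(x)
}

#' Rarefy a ribotype count vector
#'
#' Draws `m` sequences uniformly without replacement from the multiset
#' described by `counts` (equivalently, a multivariate hypergeometric draw).
#'
#' @param counts Named (or unnamed) non-negative integer vector of ribotype
#'   counts.
#' @param m Subsampling depth; must not exceed `sum(counts)`.
#' @param seed Integer seed; every draw is reproducible.
#' @param n_draws Number of independent draws.
#' @return An `n_draws` x `length(counts)` integer matrix; each row sums to
#'   `m`. Column names follow `names(counts)`.
#' @export
rarefy <- function(counts, m, seed, n_draws = 1) {
  total <- sum(counts)
  if (m > total) {
    abort(sprintf("cannot subsample %d from %d sequences", m, total))
  }
  if (m <= 0) abort("m must be positive")
  pool <- rep.int(seq_along(counts), counts)
  draws <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_draws), function(i) {
      tabulate(sample(pool, m), nbins = length(counts))
    }, integer(length(counts))))
  })
  colnames(draws) <- names(counts)
  draws
}

#' Ribotype diversity of a (sub)sample
#'
#' The one statistic used throughout: the number of distinct ribotypes
#' divided by the number of sequences, `D = k / m`.
#'
#' @param x A count vector, or a matrix of draws (rows = draws).
#' @return `D` per draw (numeric scalar or vector).
#' @export
ribotype_diversity <- function(x) {
  if (is.matrix(x)) {
    m <- rowSums(x)
    if (any(m == 0)) abort("empty subsample")
    return(rowSums(x > 0) / m)
  }
  m <- sum(x)
  if (m == 0) abort("empty subsample")
  sum(x > 0) / m
}

#' Rarefied ribotype diversity per sample and homeolog
#'
#' Splits the classified counts by homeolog class (parental type) within
#' each region, chooses the subsampling depth by the second-lowest rule
#' within each homeolog x region dataset, rarefies every sample that meets
#' the depth and computes `D`. With `n_draws > 1`, `D` is the mean over
#' draws and its SD is reported.
#'
#' @param classified A `classified_tbl` (singletons removed).
#' @param seed Integer master seed (per-sample draw seeds are derived).
#' @param n_draws Draws per sample (default 1, matching a single-subsample design).
#' @param samples Optional sample sheet for metadata join.
#' @return A tibble of class `diversity_tbl`: `sample_id`, `homeolog`,
#'   `region`, `total` (pre-subsampling), `k_full` (pre-subsampling ribotype
#'   count), `raw_ratio` (k_full/total), `m`, `k`, `D`, `D_sd`, `seed`,
#'   `n_draws`. Samples excluded by the depth rule are absent; the excluded
#'   ids are in attribute `"excluded"`.
#' @export
rarefied_diversity <- function(classified, seed, n_draws = 1, samples = NULL) {
  check_df_cols(classified, c("sample_id", "ribotype_id", "count",
                              "assignment"), "classified")
  dat <- classified |>
    filter(!(.data$assignment %in% c("AMBIGUOUS", "TOO_SHORT")),
           .data$count > 0) |>
    rename(homeolog = "assignment")
  groups <- dat |> distinct(.data$homeolog, .data$region)
  excluded <- character()

  out <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    sub <- dat |>
      filter(.data$homeolog == groups$homeolog[g],
             .data$region == groups$region[g])
    totals <- sub |>
      group_by(.data$sample_id) |>
      summarise(total = sum(.data$count), .groups = "drop")
    if (nrow(totals) < 2) return(NULL)
    depth <- choose_subsample_depth(totals)
    excluded <<- c(excluded, depth$excluded)
    keep <- setdiff(totals$sample_id, depth$excluded)
    seeds <- derive_seeds(seed + g, length(keep))
    purrr::map_dfr(seq_along(keep), function(i) {
      cs <- sub |> filter(.data$sample_id == keep[i])
      counts <- setNames(cs$count, cs$ribotype_id)
      draws <- rarefy(counts, depth$m, seed = seeds[i], n_draws = n_draws)
      D <- ribotype_diversity(draws)
      tibble::tibble(
        sample_id = keep[i], homeolog = groups$homeolog[g],
        region = groups$region[g],
        total = sum(counts), k_full = sum(counts > 0),
        raw_ratio = sum(counts > 0) / sum(counts),
        m = depth$m, k = mean(rowSums(draws > 0)), D = mean(D),
        D_sd = if (n_draws > 1) sd(D) else NA_real_,
        seed = seeds[i], n_draws = n_draws)
    })
  })
  if (!is.null(samples) && nrow(out) > 0) {
    meta_cols <- intersect(c("sample_id", "genotype", "cross", "generation",
                             "template"), names(samples))
    out <- left_join(out, distinct(samples[meta_cols]), by = "sample_id")
  }
  attr(out, "excluded") <- unique(excluded)
  class(out) <- c("diversity_tbl", class(out))
  out
}

#' Depth-bias diagnostic: diversity vs sequencing depth
#'
#' Pearson correlation (with two-sided p from the t transform) between each
#' sample's original total sequence count and (a) the pre-subsampling
#' ribotype/total ratio, (b) the post-subsampling rarefied `D` — the
#' before/after comparison showing how much of the diversity signal is
#' depth artefact.
#'
#' @param div A `diversity_tbl` from [rarefied_diversity()] (DNA and cDNA
#'   samples pooled).
#' @return A tibble of class `correlation_tbl` with rows `pre_subsampling`
#'   and `post_subsampling`: `stage`, `R`, `p_value`, `n`, `flag`.
#' @export
depth_bias_correlation <- function(div) {
  check_df_cols(div, c("total", "raw_ratio", "D"), "div")
  if (nrow(div) < 3) abort("need at least 3 samples for the correlation")
  one <- function(stage, y) {
    if (sd(y) == 0 || sd(div$total) == 0) {
      return(tibble::tibble(stage = stage, R = NA_real_, p_value = NA_real_,
                            n = nrow(div), flag = "zero_variance"))
    }
    ct <- cor.test(div$total, y, method = "pearson")
    tibble::tibble(stage = stage, R = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(div), flag = NA_character_)
  }
  out <- bind_rows(one("pre_subsampling", div$raw_ratio),
                   one("post_subsampling", div$D))
  class(out) <- c("correlation_tbl", class(out))
  out
}

#' One-way ANOVA of diversity across generations
#'
#' Classical fixed-effects one-way ANOVA:
#' `F = MS_between / MS_within`, p from the F distribution. Groups are
#' typically the hybrid generations (parents included as levels); the
#' responses are genotype-level diversity values.
#'
#' @param data A data frame.
#' @param formula A two-sided formula `response ~ group`.
#' @return An object of class `anova_oneway` with elements `F`,
#'   `df_between`, `df_within`, `p_value`, `group_means`, `levels`, `flag`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
anova_one_way <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- mf[[1]]
  g <- factor(mf[[2]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (length(y) - nlevels(g) < 1) abort("need at least 1 residual df")
  fit <- lm(y ~ g)
  # exact fits are detected below on the sums of squares; silence the
  # corresponding anova.lm() warning
  at <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  gm <- tapply(y, g, mean)
  gm <- setNames(as.vector(gm), names(gm))
  flag <- NA_character_
  Fv <- at$`F value`[1]
  pv <- at$`Pr(>F)`[1]
  # degenerate inputs: detect vanishing sums of squares on a relative
  # scale (exact-fit residuals come back as floating noise, not zero)
  ssb <- at$`Sum Sq`[1]
  ssw <- at$`Sum Sq`[2]
  eps <- 1e-12 * max(sum(y^2), .Machine$double.xmin)
  if (ssb <= eps && ssw <= eps) {        # all observations equal
    Fv <- 0
    pv <- 1
  } else if (ssw <= eps) {               # unequal means, no within variance
    Fv <- NA_real_
    pv <- NA_real_
    flag <- "zero_within_variance"
  }
  structure(list(F = Fv, df_between = at$Df[1], df_within = at$Df[2],
                 p_value = pv, group_means = gm, levels = levels(g),
                 flag = flag),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}
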