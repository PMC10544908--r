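#' Tidy a one-way ANOVA result
#'
#' @param x An `anova_oneway` object.
#' @param ... Unused.
#' @return One row per group: `group`, `mean`, plus the shared `F`,
#'   `df_between`, `df_within`, `p_value` in [glance()].
#' @export
tidy.anova_oneway <- function(x, ...) {
  tibble::tibble(group = x$levels, mean = unname(x$group_means[x$levels]))
}

#' @rdname tidy.anova_oneway
#' @export
glance.anova_oneway <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value,
                 flag = x$flag)
}

#' Tidy the depth-bias correlation table
#'
#' @param x A `correlation_tbl`.
#' @param ... Unused.
#' @return The underlying tibble (already tidy).
#' @export
tidy.correlation_tbl <- function(x, ...) {
  tibble::as_tibble(x)
}
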