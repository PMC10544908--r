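#' Bar chart of parental-type proportions (DNA vs cDNA)
#'
#' Stacked parental-type proportions per group with one panel per template
#' and region, SD error bars on the dominant segment — the standard
#' visualisation of nucleolar dominance: genomic representation next to
#' expressed representation.
#'
#' @param object A `dominance_summary` from [aggregate_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dominance_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$generation, y = .data$mean_p,
                               fill = .data$parental_type)) +
    ggplot2::geom_col(position = "stack", colour = "grey20",
                      linewidth = 0.2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_p - .data$sd_p, 0),
                   ymax = pmin(.data$mean_p + .data$sd_p, 1)),
      data = ~ dplyr::slice_max(dplyr::group_by(
        .x, .data$cross, .data$generation, .data$template, .data$region),
        .data$mean_p, n = 1),
      width = 0.25, linewidth = 0.3) +
    ggplot2::facet_grid(region ~ template) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "mean proportion of sequences",
                  fill = "parental type") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dominance_summary
#' @param summaries A `dominance_summary`.
#' @export
plot_dominance <- function(summaries, ...) {
  autoplot.dominance_summary(summaries, ...)
}

#' Grouped bars of rarefied ribotype diversity
#'
#' Mean rarefied diversity `D` per generation and homeolog with SD error
#' bars over genotypes, faceted by region.
#'
#' @param object A `diversity_tbl` from [rarefied_diversity()] carrying
#'   `generation` metadata.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diversity_tbl <- function(object, ...) {
  check_df_cols(object, c("generation", "homeolog", "region", "D"), "object")
  dat <- object |>
    group_by(.data$generation, .data$homeolog, .data$region) |>
    summarise(mean_D = mean(.data$D),
              sd_D = ifelse(n() > 1, sd(.data$D), 0), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$mean_D,
                                    fill = .data$homeolog)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7, colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_D - .data$sd_D, 0),
                   ymax = .data$mean_D + .data$sd_D),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$region) +
    ggplot2::labs(x = NULL, y = "ribotype diversity (k / m)",
                  fill = "homeolog") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.diversity_tbl
#' @param div A `diversity_tbl`.
#' @export
plot_diversity <- function(div, ...) {
  autoplot.diversity_tbl(div, ...)
}
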