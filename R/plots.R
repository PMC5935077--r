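# ggplot2 views of the main result types.

#' @rdname ordinate_nmds
#' @param object An `nmds_ord` object.
#' @param groups Optional named vector or tibble mapping `sample_id` to a
#'   grouping (site, region, class) used for colour.
#' @export
autoplot.nmds_ord <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      df <- dplyr::left_join(df, groups, by = "sample_id")
      grp <- setdiff(names(groups), "sample_id")[1]
    } else {
      df$group <- as.character(groups[df$sample_id])
      grp <- "group"
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nmds1, y = .data$nmds2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "nMDS 1", y = "nMDS 2",
      subtitle = sprintf("Kruskal stress-1 = %.3f", object$stress)
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[grp]]))
  }
}

#' @rdname run_scan
#' @param object An `indicator_scan` object.
#' @export
autoplot.indicator_scan <- function(object, ...) {
  df <- object$results
  alpha <- object$summary$corrected_alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope, y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "regression slope", y = expression(-log[10](p)),
      colour = "passes", subtitle = sprintf("Bonferroni-corrected alpha = %.3g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Tile plot of modal outcome calls per design cell
#'
#' @param summary The tibble from [outcome_summary()].
#' @return A ggplot: origin site by destination site, filled by modal call.
#' @export
plot_outcome_grid <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$destination_site, y = .data$origin_site,
                                        fill = .data$modal_call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::labs(x = "destination site", y = "origin site", fill = "modal call") +
    ggplot2::theme_minimal()
}

#' Stacked taxon bar plot of aggregated relative abundances
#'
#' @param agg The tibble from [aggregate_display_taxa()].
#' @return A ggplot of per-sample stacked relative abundances by taxon.
#' @export
plot_taxa_bars <- function(agg) {
  long <- tidyr::pivot_longer(agg, -"taxon", names_to = "sample_id", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
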