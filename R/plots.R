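#' Scatter plot of one cross-species analysis
#'
#' Draws the classic comparative-composition scatter (e.g. genome size
#' against genomic GC%) for one analysis of the suite, annotated with the
#' Spearman coefficient and p-value, salmonid-flagged species highlighted.
#'
#' @param records Species tibble.
#' @param x_var,y_var Column names (`"c_value_pg"` allowed, see
#'   [correlate()]).
#' @param method Correlation method for the annotation.
#' @return A ggplot object.
#' @export
plot_species_scatter <- function(records, x_var, y_var, method = "spearman") {
  d <- tibble::tibble(
    x = derived_variable(records, x_var),
    y = derived_variable(records, y_var),
    salmonid = purrr::map_lgl(records$lineage_flags %||%
                                rep(list(character(0)), nrow(records)),
                              ~ "salmonid" %in% .x)
  )
  d <- dplyr::filter(d, !is.na(.data$x), !is.na(.data$y))
  ct <- correlate(records, x_var, y_var, method = method)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$salmonid), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey25", `TRUE` = "firebrick"),
      guide = if (any(d$salmonid)) "legend" else "none"
    ) +
    ggplot2::labs(
      x = x_var, y = y_var,
      subtitle = sprintf("%s rho = %.3f, p = %.2g, n = %d",
                         method, ct$coefficient, ct$p_value, ct$n)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-group consensus GC across species
#'
#' Displays pooled consensus GC per TE group, split by class, in the shape
#' used to compare Class I retroelements against Class II DNA transposons.
#'
#' @param group_gc A tibble from [pool_groups_across_species()].
#' @param mode Which aggregation to plot: `"pooled"` bases or
#'   `"mean_of_species"`.
#' @return A ggplot object.
#' @export
plot_group_gc <- function(group_gc, mode = c("pooled", "mean_of_species")) {
  mode <- match.arg(mode)
  group_gc$value <- if (mode == "pooled") group_gc$gc_pooled else
    group_gc$gc_mean_of_species
  ggplot2::ggplot(
    group_gc,
    ggplot2::aes(stats::reorder(.data$group, .data$value), .data$value,
                 fill = .data$te_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(I = "#2166ac", II = "#b2182b"),
                               name = "TE class") +
    ggplot2::labs(x = "TE group", y = "consensus GC%") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gc_analysis_suite <- function(object, ...) {
  d <- tidy(object)
  d$label <- paste0(d$analysis, "\n(", d$x_var, " vs ", d$y_var, ")")
  ggplot2::ggplot(
    d, ggplot2::aes(.data$coefficient, .data$label, shape = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "correlation coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.te_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d, ggplot2::aes(.data$group, .data$gc_percent, fill = .data$te_class)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~species_id) +
    ggplot2::scale_fill_manual(values = c(I = "#2166ac", II = "#b2182b"),
                               name = "TE class") +
    ggplot2::labs(x = "TE group", y = "consensus GC%") +
    ggplot2::theme_minimal()
}
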