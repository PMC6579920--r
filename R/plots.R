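# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   geom_point labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Pan/core accumulation curves
#' @param object a [pangenome_profile()].
#' @param ... unused.
#' @export
autoplot.pangenome_profile <- function(object, ...) {
  sm <- summarise_curves(object$curves) |>
    tidyr::pivot_longer(-"k", names_to = c("set", "stat"), names_sep = "_") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot(sm, aes(x = .data$k, y = .data$mean, colour = .data$set, fill = .data$set)) +
    geom_ribbon(aes(ymin = .data$min, ymax = .data$max), alpha = 0.2, colour = NA) +
    geom_line() + geom_point() +
    labs(x = "genomes added", y = "gene clusters", colour = NULL, fill = NULL,
         title = "Pan- and core-genome accumulation") +
    theme_minimal()
}

#' k-genome spectrum barplot
#' @param profile a [pangenome_profile()].
#' @export
plot_k_spectrum <- function(profile) {
  ggplot(profile$spectrum, aes(x = factor(.data$k), y = .data$clusters)) +
    geom_col(fill = "steelblue") +
    labs(x = "present in k genomes", y = "gene clusters",
         title = "k-genome spectrum") +
    theme_minimal()
}

#' IS census heat-style barplot
#' @param census tibble from [is_census()].
#' @export
plot_is_census <- function(census) {
  ggplot(census, aes(x = .data$genome, y = .data$copies, fill = .data$element)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "full copies", fill = "element",
         title = "IS copy census") +
    theme_minimal()
}

#' ORFan positional density along normalized chromosomes
#' @param density tibble from [orfan_positions()].
#' @export
plot_orfan_density <- function(density) {
  ggplot(density, aes(x = (.data$window_start + .data$window_end) / 2e6,
                      y = .data$n_orfans)) +
    geom_col(width = diff(range(density$window_start)) / nrow(density) / 1e6,
             fill = "darkorange") +
    facet_wrap(~genome, ncol = 1) +
    labs(x = "position on normalized chromosome (Mb)", y = "ORFans per window",
         title = "ORFan positional density") +
    theme_minimal()
}

#' Functional composition of HGT genes
#' @param categories tibble from [classify_hgt_regions()].
#' @export
plot_hgt_categories <- function(categories) {
  ggplot(categories, aes(x = stats::reorder(.data$category, .data$n_genes),
                         y = .data$n_genes)) +
    geom_col(fill = "seagreen") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "genes", title = "HGT gene functional categories") +
    theme_minimal()
}
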