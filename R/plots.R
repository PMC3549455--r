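#' Plot a GC3 distribution with its Gaussian fits
#'
#' Histogram of the binned values overlaid with the fitted one-Gaussian
#' (dashed) and two-Gaussian (solid) curves.
#'
#' @param object A `mixture_comparison` from [fit_mixture_and_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_comparison <- function(object, ...) {
  h <- object$histogram
  grid <- tibble::tibble(x = seq(min(h$mid), max(h$mid), length.out = 400))
  curves <- dplyr::bind_rows(
    tibble::tibble(x = grid$x, y = mixture_curve(grid$x, object$fit1$parameters),
                   model = "one Gaussian"),
    tibble::tibble(x = grid$x, y = mixture_curve(grid$x, object$fit2$parameters),
                   model = "two Gaussians")
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    linetype = .data$model),
                       linewidth = 0.8) +
    ggplot2::labs(x = expression(GC[3] ~ "(%)"), y = "Number of genes",
                  linetype = NULL) +
    ggplot2::theme_classic()
}

#' Histogram of GC3 by chromosome size class
#'
#' @param genes Tibble with `gc3` and `size_class`.
#' @param bin_width Bin width (default 5).
#' @return A ggplot object.
#' @export
plot_gc3_by_class <- function(genes, bin_width = 5) {
  ggplot2::ggplot(dplyr::filter(genes, !is.na(.data$gc3)),
                  ggplot2::aes(x = .data$gc3, fill = .data$size_class)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            position = "stack", colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(macro = "white", micro = "black",
                                          unknown = "grey70")) +
    ggplot2::labs(x = expression(GC[3] ~ "(%)"), y = "Number of genes",
                  fill = "Chromosome class") +
    ggplot2::theme_classic()
}

#' Scatter plot of ortholog GC3 between two species
#'
#' Two-dimensional plot of per-ortholog GC3, coloured by the four
#' chromosome-class categories when present.
#'
#' @param orthologs Long tibble as in [cross_species_analysis()].
#' @param species_a,species_b The two species to plot.
#' @return A ggplot object.
#' @export
plot_ortholog_gc3 <- function(orthologs, species_a, species_b) {
  wide <- orthologs |>
    dplyr::filter(.data$species %in% c(species_a, species_b)) |>
    dplyr::select(dplyr::any_of(c("ortholog_id", "species", "gc3", "pair_group"))) |>
    tidyr::pivot_wider(names_from = "species", values_from = "gc3")
  aes <- if ("pair_group" %in% names(wide)) {
    ggplot2::aes(x = .data[[species_a]], y = .data[[species_b]],
                 colour = .data$pair_group)
  } else {
    ggplot2::aes(x = .data[[species_a]], y = .data[[species_b]])
  }
  ggplot2::ggplot(wide, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = bquote(.(species_a) ~ GC[3] ~ "(%)"),
                  y = bquote(.(species_b) ~ GC[3] ~ "(%)"),
                  colour = "Category") +
    ggplot2::theme_classic()
}
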