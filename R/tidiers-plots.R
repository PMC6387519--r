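# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment score matrix into long format
#'
#' @param x An `ssr_score_matrix`.
#' @param ... Unused.
#' @return Tibble `organism_id`, `repeat_class`, `score`, one row per cell.
#' @export
tidy.ssr_score_matrix <- function(x, ...) {
  tibble::tibble(
    organism_id = rep(x$organisms, times = length(x$classes)),
    repeat_class = rep(x$classes, each = length(x$organisms)),
    score = as.integer(x$scores)
  )
}

#' One-row summary of an enrichment score matrix
#'
#' @inheritParams tidy.ssr_score_matrix
#' @return Tibble with organism/class counts and cell tallies per score.
#' @export
glance.ssr_score_matrix <- function(x, ...) {
  tibble::tibble(
    n_organisms = length(x$organisms),
    n_classes = length(x$classes),
    n_top10 = sum(x$scores == 3L),
    n_absent = sum(x$scores == -2L),
    mean_score = mean(x$scores)
  )
}

score_palette <- c(`-2` = "#d73027", `-1` = "#fdae61", `0` = "#f7f7f7",
                   `1` = "#a6bddb", `2` = "#2b8cbe", `3` = "#000000")

#' Heat map of an enrichment score matrix
#'
#' Tile plot with organisms as rows (supplied evolutionary order, top to
#' bottom) and repeat classes as columns; dark tiles mark top-10 classes,
#' red tiles near-absent ones (frequency < 10).
#'
#' @param object An `ssr_score_matrix`.
#' @param class_order Optional class ordering, e.g.
#'   `cluster_classes(object)$order`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_score_matrix <- function(object, class_order = NULL, ...) {
  df <- tidy(object)
  df$organism_id <- factor(df$organism_id, levels = rev(object$organisms))
  df$repeat_class <- factor(df$repeat_class,
                            levels = class_order %||% object$classes)
  ggplot2::ggplot(df, ggplot2::aes(.data$repeat_class, .data$organism_id,
                                   fill = factor(.data$score))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = score_palette, name = "score") +
    ggplot2::labs(x = "repeat class", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Line chart of unit-length abundance with detected peaks
#'
#' @param hist Tibble from [unit_length_histogram()], ideally filtered to a
#'   few classes.
#' @param peaks Optional matching [detect_length_preference()] output;
#'   peak spans are shaded.
#' @return A ggplot object.
#' @export
plot_length_preference <- function(hist, peaks = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(.data$units, .data$abundance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~repeat_class, scales = "free") +
    ggplot2::labs(x = "unit length (complete motif copies)",
                  y = "abundance (SSR count)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$peak_start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Stacked motif-size composition per genomic region
#'
#' @param composition Tibble from [region_composition()].
#' @return A ggplot object: stacked percentage bars of SSR bases by motif
#'   size for each region.
#' @export
plot_region_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$region, .data$pct,
                               fill = factor(.data$k))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "motif size") +
    ggplot2::labs(x = NULL, y = "% of SSR bases") +
    ggplot2::theme_minimal()
}
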