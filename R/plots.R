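#' Heatmap of a species distance matrix
#'
#' @param object A `domtax_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domtax_dist
#' @export
autoplot.domtax_dist <- function(object, ...) {
  ids <- object$species_ids
  long <- tibble::as_tibble(object$values, rownames = "from") |>
    tidyr::pivot_longer(!"from", names_to = "to", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$to, ids), y = factor(.data$from, rev(ids)),
    fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "distance",
      title = paste(object$statistical_model, object$distance_model, sep = " x ")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Plot a spanning tree on a circular layout
#'
#' Nodes are placed on a circle (optionally colored by a taxonomy rank) and
#' tree edges drawn as chords; a quick structural view, not a tree layout.
#'
#' @param object A `domtax_mst` object.
#' @param taxonomy Optional taxonomy tibble for node coloring.
#' @param rank Rank used for coloring, default `"phylum"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domtax_mst
#' @export
autoplot.domtax_mst <- function(object, taxonomy = NULL, rank = "phylum", ...) {
  ids <- sort(object$species_ids)
  theta <- 2 * pi * (seq_along(ids) - 1) / length(ids)
  pos <- tibble::tibble(
    species_id = ids, x = cos(theta), y = sin(theta)
  )
  if (!is.null(taxonomy)) {
    pos$taxon <- taxonomy[[rank]][match(ids, taxonomy$species_id)]
  } else {
    pos$taxon <- "species"
  }
  seg <- object$edges |>
    dplyr::left_join(pos, by = c(from = "species_id")) |>
    dplyr::left_join(pos, by = c(to = "species_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
        linewidth = 1 - .data$weight
      ),
      color = "grey60"
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$taxon),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(color = rank)
}

#' Per-taxon isolation plot for a cluster report
#'
#' Bars show each taxon's species count, with the isolated part (species
#' outside the taxon's main group) highlighted.
#'
#' @param object A `taxon_cluster_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot taxon_cluster_report
#' @export
autoplot.taxon_cluster_report <- function(object, ...) {
  counts <- object$counts |>
    dplyr::mutate(main = .data$T - .data$S) |>
    tidyr::pivot_longer(
      c("main", "S"), names_to = "part", values_to = "n_species"
    ) |>
    dplyr::mutate(part = ifelse(.data$part == "S", "isolated", "main group"))
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$taxon, y = .data$n_species, fill = .data$part
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "species", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot plot comparing model combinations across the three standards
#'
#' The machine analogue of eyeballing a comparison figure: one panel per
#' agreement standard, combinations ordered by value, best values lowest.
#'
#' @param metrics Metrics tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_combination_metrics <- function(metrics) {
  long <- compare_combinations(metrics)
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$label, .data$value), y = .data$value,
    color = !is.na(.data$flag)
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~ .data$standard, scales = "free_y") +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "red", `FALSE` = "grey30"), guide = "none"
    ) +
    ggplot2::labs(x = NULL, y = "value (lower is better)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
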