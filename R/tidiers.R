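#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MST into an edge tibble
#'
#' @param x A `sat_mst`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `weight` (mutational steps) plus the
#'   species of both endpoints.
#' @export
tidy.sat_mst <- function(x, ...) {
  sp <- setNames(x$nodes$species, x$nodes$id)
  dplyr::mutate(x$edges,
                from_species = unname(sp[.data$from]),
                to_species = unname(sp[.data$to]))
}

#' One-row summary of an MST
#'
#' @param x A `sat_mst`.
#' @param ... Unused.
#' @return Tibble with `n_haplotypes`, `n_edges`, `n_step_nodes`,
#'   `total_weight`, `max_edge_weight`.
#' @export
glance.sat_mst <- function(x, ...) {
  tibble(
    n_haplotypes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_step_nodes = x$n_steps,
    total_weight = sum(x$edges$weight),
    max_edge_weight = if (nrow(x$edges)) max(x$edges$weight) else NA_integer_
  )
}

#' Tidy a cluster set into its member table
#'
#' @param x A `sat_clusters`.
#' @param ... Unused.
#' @return Tibble mapping each haplotype to its cluster, joined with the
#'   cluster summary.
#' @export
tidy.sat_clusters <- function(x, ...) {
  dplyr::left_join(x$members, x$clusters, by = "cluster")
}

#' One-row summary of a cluster set
#'
#' @param x A `sat_clusters`.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_members`, `threshold`.
#' @export
glance.sat_clusters <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_members = nrow(x$members),
    threshold = x$threshold
  )
}

#' One-row summary of a pipeline report
#'
#' @param x A `sat_report`.
#' @param ... Unused.
#' @return Tibble with species, haplotype, cluster and MST totals.
#' @export
glance.sat_report <- function(x, ...) {
  tibble(
    n_species = length(unique(x$haplotypes$species)),
    n_haplotypes = nrow(x$haplotypes),
    n_clusters = nrow(x$clusters),
    mst_weight = sum(x$mst$edges$weight)
  )
}

#' Plot a haplotype minimum spanning tree
#'
#' Haplotype nodes are drawn as circles (Illumina) or squares (PCR) sized by
#' abundance and coloured by species; mutational-step nodes are small black
#' dots.
#'
#' @param object A `sat_mst`.
#' @param ... Unused.
#' @param layout_seed Seed for the force-directed layout.
#' @return A ggplot object.
#' @export
autoplot.sat_mst <- function(object, ..., layout_seed = 1L) {
  g <- object$graph
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- node_table(object) |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    x = nodes$x[match(el[, 1], nodes$id)],
    y = nodes$y[match(el[, 1], nodes$id)],
    xend = nodes$x[match(el[, 2], nodes$id)],
    yend = nodes$y[match(el[, 2], nodes$id)]
  )
  hap <- dplyr::filter(nodes, .data$step == 0L)
  stepn <- dplyr::filter(nodes, .data$step == 1L)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = stepn, ggplot2::aes(x = .data$x, y = .data$y),
      size = 1, colour = "black"
    ) +
    ggplot2::geom_point(
      data = hap,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$abundance,
                   colour = .data$species,
                   shape = .data$origin),
      alpha = 0.9
    ) +
    ggplot2::scale_shape_manual(
      values = c(illumina = 16, pcr = 15), na.value = 16
    ) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "abundance", colour = "species", shape = "origin")
}

#' Plot per-column information content of an alignment
#'
#' Bar height is the sequence-logo information content (bits) per column,
#' filled by the majority base.
#'
#' @param object A `sat_logo` tibble from [logo_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sat_logo <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(dplyr::all_of(paste0("f_", DNA_BASES)),
                        names_to = "base", values_to = "freq") |>
    dplyr::mutate(base = sub("^f_", "", .data$base)) |>
    dplyr::group_by(.data$column) |>
    dplyr::slice_max(.data$freq, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$R_bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot the per-species diversity summary
#'
#' @param object A `sat_diversity` tibble.
#' @param ... Unused.
#' @return A ggplot object comparing nucleotide diversity across species.
#' @export
autoplot.sat_diversity <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$species, .data$pi),
                               y = .data$pi, fill = .data$origin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(pi)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
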