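# ggplot2 views of the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.verification_result <- function(object, ...) {
  stopifnot(nrow(object$verified) > 0)
  df <- tibble(size = object$verified$n_proteins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = function(l) seq(floor(l[1]), ceiling(l[2]))) +
    ggplot2::labs(x = "verified complex size (proteins)",
                  y = "number of complexes",
                  title = "Size distribution of verified complexes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.complex_eval <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$matches, ggplot2::aes(x = .data$best_v)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, fill = "grey40") +
    ggplot2::geom_vline(xintercept = s$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      x = "best overlap score V per prediction",
      y = "predictions",
      title = sprintf("Overlap with known complexes (precision %.2f, recall %.2f)",
                      s$precision, s$recall)) +
    ggplot2::theme_minimal()
}

#' Plot the PPI/DDI topology of one verified complex
#'
#' Draws the member proteins with their active PPIs (thick edges) and the
#' mediating DDIs (thin dashed edges labelled with the two domain
#' instances), the package's analog of a complex topology diagram.
#'
#' @param verified A verified-complex tibble.
#' @param complex_id Which complex to draw; default the first row.
#' @return A ggplot object.
#' @export
plot_complex_topology <- function(verified, complex_id = NULL) {
  stopifnot(nrow(verified) > 0)
  row <- if (is.null(complex_id)) verified[1, ] else {
    verified[verified$complex_id == complex_id, ]
  }
  if (nrow(row) != 1) abort("Complex not found.")
  mem <- row$members[[1]]
  g <- igraph::graph_from_data_frame(as.data.frame(row$ppi_edges[[1]]),
                                     directed = FALSE, vertices = mem)
  xy <- with_rng_seed(1, igraph::layout_with_fr(g))  # layout only
  nodes <- tibble(protein = mem, x = xy[, 1], y = xy[, 2])
  e <- row$ppi_edges[[1]] |>
    left_join(nodes, by = c(protein_a = "protein")) |>
    rename(xa = "x", ya = "y") |>
    left_join(nodes, by = c(protein_b = "protein")) |>
    rename(xb = "x", yb = "y")
  d <- row$ddi_edges[[1]] |>
    left_join(nodes, by = c(protein_i = "protein")) |>
    rename(xa = "x", ya = "y") |>
    left_join(nodes, by = c(protein_j = "protein")) |>
    rename(xb = "x", yb = "y") |>
    mutate(label = sprintf("%s/%d-%s/%d", .data$domain_i, .data$copy_i,
                           .data$domain_j, .data$copy_j))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          linewidth = 1.6, colour = "grey30") +
    ggplot2::geom_segment(data = d,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          linewidth = 0.4, linetype = "dashed",
                          colour = "tomato") +
    ggplot2::geom_label(data = d,
                        ggplot2::aes(x = (.data$xa + .data$xb) / 2,
                                     y = (.data$ya + .data$yb) / 2,
                                     label = .data$label),
                        size = 2.6, colour = "tomato") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 9, colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$protein),
                       colour = "white", size = 2.8) +
    ggplot2::labs(title = paste0("Complex ", row$complex_id,
                                 " (objective ", row$objective, ")")) +
    ggplot2::theme_void()
}
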