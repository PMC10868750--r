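#' Plot a referral network
#'
#' Fruchterman-Reingold layout of the directed graph; vertex size scales with
#' the vertex weight (consultation share), colour with specialty, and edge
#' alpha with the edge weight.
#'
#' @param object A `"referral_network"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.referral_network <- function(object, ...) {
  g <- object$graph
  set.seed(1) # layout only
  xy <- igraph::layout_with_fr(g)
  nodes <- object$vertices |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$physician_id)],
    y = nodes$y[match(el[, 1], nodes$physician_id)],
    xend = nodes$x[match(el[, 2], nodes$physician_id)],
    yend = nodes$y[match(el[, 2], nodes$physician_id)],
    Ew = igraph::E(g)$Ew
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$Ew),
                          colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$Vw,
                                     colour = .data$specialty)) +
    ggplot2::scale_alpha(range = c(0.1, 0.7), guide = "none") +
    ggplot2::scale_size(range = c(1, 6), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Specialty")
}

#' Plot cluster-count diagnostics
#'
#' Silhouette and within-cluster sum of squares (elbow) curves from
#' [select_k()].
#'
#' @param diagnostics The `diagnostics` tibble of a [select_k()] result.
#' @return A ggplot with one panel per criterion.
#' @export
plot_k_diagnostics <- function(diagnostics) {
  diagnostics |>
    tidyr::pivot_longer(c("mean_silhouette", "wss"),
                        names_to = "criterion", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Number of clusters k", y = NULL)
}

#' Plot adjusted standardized residuals of a contingency analysis
#'
#' Tile map of the per-cell residuals with their significance tiers.
#'
#' @param object A `"contingency_analysis"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.contingency_analysis <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$column, y = .data$row,
                                 fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$tier == "ns", "", .data$tier)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Adj. residual")
}

#' Plot community sizes and composition
#'
#' Stacked bar chart of specialty composition per detected community.
#'
#' @param object A `"community_partition"`.
#' @param physicians Roster tibble (for specialty lookup).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.community_partition <- function(object, physicians = NULL, ...) {
  memb <- object$membership
  if (is.null(physicians)) {
    return(
      memb |>
        dplyr::count(.data$community) |>
        ggplot2::ggplot(ggplot2::aes(x = factor(.data$community), y = .data$n)) +
        ggplot2::geom_col() +
        ggplot2::theme_minimal() +
        ggplot2::labs(x = "Community", y = "Physicians")
    )
  }
  memb |>
    dplyr::left_join(physicians, by = "physician_id") |>
    dplyr::count(.data$community, .data$specialty) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$community), y = .data$n,
                                 fill = .data$specialty)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "Community", y = "Physicians", fill = "Specialty")
}
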