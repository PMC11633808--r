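# ggplot2 presentation of the package's result types.

raster_tibble <- function(mat, value = "value") {
  d <- dim(mat)
  out <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1])
  )
  out[[value]] <- as.vector(mat)
  out
}

#' @export
autoplot.four_colour_map <- function(object, ...) {
  d <- dim(object)
  df <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(as.vector(object[, , 1]),
                          as.vector(object[, , 2]),
                          as.vector(object[, , 3]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "TP green / FP pink / FN blue / GDC-modified yellow")
}

#' Plot a confidence map as an error-probability heat map
#'
#' @param p_error `H x W` matrix of error-class probabilities.
#' @param image Optional underlay image (currently unused; kept for API
#'   symmetry).
#' @return A ggplot.
#' @export
plot_confidence_map <- function(p_error, image = NULL) {
  df <- raster_tibble(p_error, "p_error")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$p_error)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "p(error)")
}

#' Plot a phantom slice with organ outlines
#'
#' @param slice A `list(image =, masks =)` pair from [generate_phantom()].
#' @return A ggplot.
#' @export
plot_phantom <- function(slice) {
  df <- raster_tibble(slice$image, "intensity")
  k <- dim(slice$masks)[3]
  edges <- lapply(seq_len(k), function(j) {
    e <- raster_tibble(sobel_edge(slice$masks[, , j]), "edge")
    e$organ <- organ_names(slice$masks)[j]
    dplyr::filter(e, .data$edge > 0)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::geom_tile(data = dplyr::bind_rows(edges),
                       ggplot2::aes(colour = .data$organ), fill = NA,
                       linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity", colour = "organ")
}

#' @export
autoplot.aco_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("fl_g", "fl_d", "l_gen"),
                            names_to = "loss", values_to = "value")
  df <- dplyr::filter(df, is.finite(.data$value))
  df <- dplyr::mutate(dplyr::group_by(df, .data$loss),
                      step = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "batch update", y = "loss")
}
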