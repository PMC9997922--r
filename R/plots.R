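# ggplot2 displays for landscapes, trajectories, kernels, and correlograms.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

hex_xy <- function(q, r) {
  list(x = 1.5 * q, y = sqrt(3) * (r + q / 2))
}

#' Plot a landscape's patches and barrier gaps
#'
#' @param object A `hexpop_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hexpop_landscape <- function(object, ...) {
  cl <- object$cells
  xy <- hex_xy(cl$q, cl$r)
  df <- tibble(x = xy$x, y = xy$y, patch = factor(cl$patch),
               habitat = c("none", "A", "B")[object$habitat + 1L])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$patch), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "patch", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  gaps <- object$interpatch[object$interpatch$is_gap, ]
  if (nrow(gaps)) {
    gx <- (hex_xy(cl$q[gaps$from], cl$r[gaps$from])$x +
             hex_xy(cl$q[gaps$to], cl$r[gaps$to])$x) / 2
    gy <- (hex_xy(cl$q[gaps$from], cl$r[gaps$from])$y +
             hex_xy(cl$q[gaps$to], cl$r[gaps$to])$y) / 2
    p <- p + ggplot2::geom_point(
      data = tibble(x = gx, y = gy), shape = 4, size = 2,
      colour = "black"
    )
  }
  p
}

#' Plot per-patch population trajectories
#'
#' @param object A `hexpop_sim`.
#' @param log10_scale Use a log10 vertical axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hexpop_sim <- function(object, log10_scale = TRUE, ...) {
  df <- population_trajectories(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$count,
                                        colour = factor(.data$patch))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "patch", y = "population size") +
    ggplot2::theme_minimal()
  ends <- object$config$epochs$end
  p <- p + ggplot2::geom_vline(xintercept = ends[-length(ends)],
                               linetype = "dashed", colour = "grey60")
  if (log10_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an isolation-by-distance correlogram
#'
#' @param object A `hexpop_correlogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hexpop_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid,
                                       y = .data$mean_genetic_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs)) +
    ggplot2::labs(x = "geographic distance (hexagons)",
                  y = "mean genetic distance", size = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot realized dispersal kernels
#'
#' Frequency of realized natal-to-settlement distances, by epoch.
#'
#' @param sim A `hexpop_sim`.
#' @param epochs Optional subset of epoch names.
#' @return A ggplot object.
#' @export
plot_dispersal_kernel <- function(sim, epochs = NULL) {
  k <- sim$kernels
  if (!is.null(epochs)) k <- k[k$epoch %in% epochs, ]
  ggplot2::ggplot(k, ggplot2::aes(x = .data$distance, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~epoch, scales = "free_y") +
    ggplot2::labs(x = "dispersal distance (hexagons)", y = "dispersers") +
    ggplot2::theme_minimal()
}
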