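#' Plot a brood trajectory
#'
#' Path plot of one or more broods, colored by behavioral state when a
#' `state` column is present, over an optional landcover background.
#'
#' @param fixes Fix table (optionally with `state`).
#' @param landscape Optional `recursel_landscape` drawn as background.
#' @return A ggplot object.
#' @export
plot_track <- function(fixes, landscape = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(landscape)) {
    cen <- cell_centers(landscape)
    bg <- expand.grid(y = cen$y, x = cen$x)
    bg$landcover <- factor(as.vector(landscape$landcover),
                           levels = landcover_classes(),
                           labels = names(landcover_classes()))
    p <- p + ggplot2::geom_raster(
      data = bg, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$landcover),
      alpha = 0.4)
  }
  aes_pt <- if ("state" %in% names(fixes)) {
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$state)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
  p +
    ggplot2::geom_path(data = fixes, ggplot2::aes(x = .data$x, y = .data$y,
                                                  group = .data$brood_id),
                       color = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = fixes, aes_pt, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~brood_id) +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @export
autoplot.recursel_hmm_fit <- function(object, xmax = NULL, ...) {
  p <- object$params
  xmax <- xmax %||% (max(p$gamma_mean) + 3 * max(p$gamma_sd))
  grid <- seq(1, xmax, length.out = 400)
  dens <- purrr::map_dfr(1:3, function(k) {
    tibble::tibble(
      state = hmm_state_labels()[k], x = grid,
      density = dgamma(grid, shape = gamma_shape(p$gamma_mean[k], p$gamma_sd[k]),
                       scale = gamma_scale(p$gamma_mean[k], p$gamma_sd[k])))
  })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step length (m)", y = "density",
                  title = "Fitted state-specific step-length distributions")
}

#' Plot a recursion raster
#'
#' Heatmap of a 0-100 recursion map (0 = strongest recursion, dark).
#'
#' @param raster A `recursel_raster`.
#' @return A ggplot object.
#' @export
plot_recursion_raster <- function(raster) {
  stopifnot(inherits(raster, "recursel_raster"))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  df <- expand.grid(
    y = raster$origin[2] + (seq_len(nr) - 0.5) * raster$cell_size,
    x = raster$origin[1] + (seq_len(nc) - 0.5) * raster$cell_size)
  df$value <- as.vector(raster$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1, limits = c(0, 100)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "0-100 scale",
                  title = sprintf("%s / %s / %s", raster$brood_id,
                                  raster$state, raster$metric))
}

#' @export
autoplot.recursel_model_table <- function(object, ...) {
  if (length(object$coefficients) == 0) {
    abort("no models within the delta-AICc cutoff to plot")
  }
  df <- purrr::imap_dfr(object$coefficients,
                        ~ dplyr::mutate(.x, model = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   color = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "selection coefficient (95% CI)", y = NULL)
}
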