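#' Plot a fitted detection function
#'
#' Scaled histogram of the observed (or bin-midpoint) distances with the
#' fitted detection curve at the mean covariate values overlaid.
#'
#' @param object A `"detection_fit"` with stored distances.
#' @param bins Histogram bin count for exact distances.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_fit
#' @export
autoplot.detection_fit <- function(object, bins = 12, ...) {
  if (object$key == "strip") {
    stop_mdsm("Strip platforms have no detection curve to plot.",
              "mdsm_config_error")
  }
  parts <- theta_parts(object$theta[!grepl("^g0:", names(object$theta))],
                       object$key,
                       sum(grepl("^sigma:", names(object$theta))))
  sigma0 <- exp(parts$theta_sigma[1])
  xx <- seq(0, object$w, length.out = 200)
  curve_df <- tibble::tibble(
    distance = xx,
    g = detection_g(xx, object$key, sigma0, parts$shape))
  breaks <- object$cutpoints %||%
    seq(0, object$w, length.out = bins + 1)
  if (!is.null(object$distances) && length(object$distances) > 0) {
    h <- graphics::hist(object$distances, breaks = breaks, plot = FALSE)
    # rescale so bar areas integrate like the conditional distance density
    scale <- mean(detection_g(object$distances, object$key, sigma0,
                              parts$shape)) / mean(h$density + 1e-12)
    hist_df <- tibble::tibble(mid = h$mids, height = h$density * scale,
                              width = diff(breaks))
  } else {
    hist_df <- NULL
  }
  p <- ggplot2::ggplot()
  if (!is.null(hist_df)) {
    p <- p + ggplot2::geom_rect(
      data = hist_df,
      ggplot2::aes(xmin = .data$mid - .data$width / 2,
                   xmax = .data$mid + .data$width / 2,
                   ymin = 0, ymax = .data$height),
      fill = "grey80", colour = "grey40")
  }
  p + ggplot2::geom_line(
    data = curve_df, ggplot2::aes(x = .data$distance, y = .data$g),
    linewidth = 1) +
    ggplot2::labs(x = "Distance", y = "Detection probability",
                  title = sprintf("Platform %s (%s)", object$platform_id,
                                  object$key)) +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted segment counts
#'
#' @param object A `"dsm_fit"`.
#' @param ... Unused.
#' @return A ggplot object, faceted by platform.
#' @method autoplot dsm_fit
#' @export
autoplot.dsm_fit <- function(object, ...) {
  df <- tibble::tibble(
    platform_id = object$segments$platform_id,
    observed = object$segments$n,
    fitted = as.numeric(predict(object$gam, type = "response")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~platform_id) +
    ggplot2::labs(x = "Fitted E[n]", y = "Observed n") +
    ggplot2::theme_minimal()
}

#' Map a predicted density surface
#'
#' Tile maps of per-cell density and CV when the grid has `x`/`y`
#' coordinates, otherwise a ranked per-cell density plot.
#'
#' @param object An `"abundance_estimate"`.
#' @param grid The prediction grid used (supplies coordinates).
#' @param what `"density"` or `"cv"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abundance_estimate
#' @export
autoplot.abundance_estimate <- function(object, grid = NULL,
                                        what = c("density", "cv"), ...) {
  what <- match.arg(what)
  cells <- object$cells
  if (!is.null(grid) && all(c("x", "y") %in% names(grid))) {
    if (!("cell_id" %in% names(grid))) grid$cell_id <- seq_len(nrow(grid))
    cells <- dplyr::left_join(cells,
                              dplyr::select(grid, "cell_id", "x", "y"),
                              by = "cell_id")
    return(
      ggplot2::ggplot(cells,
                      ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[what]])) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::coord_equal() +
        ggplot2::labs(fill = what) +
        ggplot2::theme_minimal())
  }
  cells$rank <- rank(cells$density)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$rank, y = .data[[what]])) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}
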