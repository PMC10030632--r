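#' Plot selected aperture-movie frames
#'
#' @param object An `aperture_movie`.
#' @param frames Frame indices to show (default 6 evenly spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aperture_movie <- function(object, frames = NULL, ...) {
  n <- dim(object$frames)[3]
  if (is.null(frames)) frames <- unique(round(seq(1, n, length.out = 6)))
  df <- purrr::map(frames, function(f) {
    tibble(x = rep(object$px, times = length(object$py)),
           y = rep(object$py, each = length(object$px)),
           value = as.vector(object$frames[, , f]),
           frame = f)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "grey20", high = "white",
                                 guide = "none") +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = "Bar aperture frames")
}

#' Plot a cortical magnification curve
#'
#' @param object A `cmag_curve` from [areal_cmag()].
#' @param reference Add the Horton-Hoyt reference curve?
#' @param scale,e0 Reference-law constants.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmag_curve <- function(object, reference = TRUE, scale = 17.3,
                                e0 = 0.75, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$m)) +
    ggplot2::geom_line(linewidth = 0.8, color = "#2166ac") +
    ggplot2::geom_point(color = "#2166ac") +
    ggplot2::labs(x = "Eccentricity (deg)",
                  y = expression(paste("Areal magnification (",
                                       mm^2 / deg^2, ")")))
  if (reference) {
    ref <- tibble(r = seq(min(object$r), max(object$r), length.out = 100))
    ref$m <- horton_hoyt_areal(ref$r, scale, e0)
    p <- p + ggplot2::geom_line(data = ref, linetype = "dashed",
                                color = "black")
  }
  p
}

#' Plot a bootstrapped wedge-area fit
#'
#' @param object A `wedge_fit` from [bootstrap_linear_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wedge_fit <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(.data$half_width)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.25, fill = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_area)) +
    ggplot2::labs(x = "Wedge half-width (deg)",
                  y = expression(paste("Surface area (", mm^2, ")")))
}

#' Flat-map view of a synthetic hemisphere's polar-angle map
#'
#' @param hemi A [build_hemisphere()] result.
#' @param what Column of the retinotopy to color by (default `angle`).
#' @return A ggplot object.
#' @export
plot_flatmap <- function(hemi, what = "angle") {
  df <- dplyr::bind_cols(hemi$mesh$vertices[, c("x_mm", "y_mm")],
                         hemi$retinotopy[what])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   color = .data[[what]])) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)", color = what)
}

#' Per-group asymmetry index plot
#'
#' @param result A `pipeline_result`.
#' @return A ggplot object with one panel per index.
#' @export
plot_asymmetry_indices <- function(result) {
  df <- tidyr::pivot_longer(result$subjects, c("hva", "vma"),
                            names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "#b2182b") +
    ggplot2::facet_wrap(~index, scales = "free_y",
                        labeller = ggplot2::as_labeller(toupper)) +
    ggplot2::labs(x = NULL, y = "Index (mean-normalized % difference)")
}
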