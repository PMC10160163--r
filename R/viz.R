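#' Overlay rendering configuration
#'
#' @param threshold minimum speed (cm/s) for a vector to be drawn; the
#'   default 4 cm/s suppresses velocity noise and vector clutter.
#' @param scale arrow length in display pixels per cm/s.
#' @param stride subsampling stride of the vector grid (>= 1).
#' @param colormap ggplot2 continuous colour option (viridis family).
#' @return An object of class `overlay_config`.
#' @export
overlay_config <- function(threshold = 4, scale = 0.25, stride = 2, colormap = "viridis") {
  stopifnot(threshold >= 0, stride >= 1, scale > 0)
  structure(list(threshold = threshold, scale = scale, stride = as.integer(stride),
                 colormap = colormap), class = "overlay_config")
}

#' Arrow data for a vector overlay frame
#'
#' Returns the drawable arrows of one phase: masked pixels on the
#' subsampled grid whose speed strictly exceeds the display threshold, with
#' display lengths proportional to speed.
#'
#' @param flow a [flow_field()] (cm/s).
#' @param mask a [blood_pool_mask()].
#' @param phase 0-based phase index.
#' @param cfg an [overlay_config()].
#' @return A tibble `(row, col, vx, vy, speed, dr, dc)`; `dr`/`dc` are the
#'   arrow extents in display pixels.
#' @export
overlay_arrows <- function(flow, mask, phase, cfg = overlay_config()) {
  d <- dim(flow$vx)
  vx <- flow$vx[phase + 1L, , ]; vy <- flow$vy[phase + 1L, , ]
  m <- mask$labels[phase + 1L, , ] > 0L
  keep <- matrix(FALSE, d[2], d[3])
  keep[seq(1L, d[2], cfg$stride), seq(1L, d[3], cfg$stride)] <- TRUE
  sp <- sqrt(vx^2 + vy^2)
  sel <- m & keep & (sp > cfg$threshold)
  idx <- which(sel, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 vx = vx[sel], vy = vy[sel], speed = sp[sel],
                 dr = cfg$scale * vy[sel], dc = cfg$scale * vx[sel])
}

#' Plot one cine frame with its velocity-vector overlay
#'
#' @param cine a [cine_sequence()].
#' @param flow a [flow_field()].
#' @param mask a [blood_pool_mask()].
#' @param phase 0-based phase index.
#' @param cfg an [overlay_config()].
#' @return A ggplot object; arrow length and colour are monotone in speed.
#' @export
plot_flow_overlay <- function(cine, flow, mask, phase, cfg = overlay_config()) {
  fr <- cine$frames[phase + 1L, , ]
  img <- tibble::tibble(
    row = as.vector(row(fr)) - 1L, col = as.vector(col(fr)) - 1L,
    intensity = as.vector(fr))
  arrows <- overlay_arrows(flow, mask, phase, cfg)
  p <- ggplot2::ggplot(img, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("phase %d", phase))
  if (nrow(arrows) > 0)
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$col, y = .data$row,
                   xend = .data$col + .data$dc, yend = .data$row + .data$dr,
                   colour = .data$speed),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt")), linewidth = 0.3) +
      ggplot2::scale_colour_viridis_c(option = cfg$colormap, name = "cm/s")
  p
}

#' Render the vector overlay of every phase to PNG files
#'
#' @inheritParams plot_flow_overlay
#' @param out_dir output directory; one `frame_###.png` per phase.
#' @param width,height device size in pixels.
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlay <- function(cine, flow, mask, out_dir, cfg = overlay_config(),
                           width = 480, height = 480) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  T_ <- dim(cine$frames)[1]
  paths <- character(T_)
  for (t in 0:(T_ - 1)) {
    paths[t + 1] <- file.path(out_dir, sprintf("frame_%03d.png", t))
    grDevices::png(paths[t + 1], width = width, height = height)
    print(plot_flow_overlay(cine, flow, mask, t, cfg))
    grDevices::dev.off()
  }
  invisible(paths)
}

#' Histogram comparison plot of predicted vs reference speeds
#'
#' @param pred_hist,ref_hist tibbles from [velocity_histogram()].
#' @return A ggplot object.
#' @export
plot_velocity_histograms <- function(pred_hist, ref_hist) {
  both <- rbind(cbind(pred_hist, source = "prediction"),
                cbind(ref_hist, source = "reference"))
  ggplot2::ggplot(both, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                     y = .data$mass, fill = .data$source)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "speed (cm/s)", y = "probability mass") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param stats an `agreement_stats` from [bland_altman()].
#' @return A ggplot object showing differences against pair means with bias
#'   and limits of agreement.
#' @export
plot_bland_altman <- function(stats) {
  df <- tibble::tibble(mean = stats$means, difference = stats$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = stats$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(stats$loa_lower, stats$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "mean of pair", y = "difference (pred - ref)") +
    ggplot2::theme_minimal()
}
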