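#' Acquisition metadata for a cine sequence
#'
#' Bundles the geometric and temporal acquisition parameters needed to convert
#' between physical velocities (cm/s) and pixel displacements per inter-frame
#' interval: in-plane pixel spacing, the time between reconstructed phases,
#' the heart rate and the number of phases covering one cardiac cycle.
#'
#' @param pixel_spacing numeric length-2, (ps_x, ps_y) in mm/pixel; x is the
#'   image-column direction, y the image-row direction.
#' @param frame_interval time between consecutive cardiac phases, seconds.
#' @param heart_rate beats per minute.
#' @param n_phases number of reconstructed phases in one cardiac cycle.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(pixel_spacing, frame_interval, heart_rate, n_phases) {
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(pixel_spacing) == 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be positive and finite", call. = FALSE)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive", call. = FALSE)
  if (!is.finite(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be positive", call. = FALSE)
  n_phases <- as.integer(n_phases)
  if (is.na(n_phases) || n_phases < 3L)
    stop("n_phases must be an integer >= 3", call. = FALSE)
  structure(
    list(pixel_spacing = pixel_spacing, frame_interval = as.numeric(frame_interval),
         heart_rate = as.numeric(heart_rate), n_phases = n_phases),
    class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("<acquisition_meta> ps = (%.3g, %.3g) mm, dt = %.4g s, HR = %.3g bpm, %d phases\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$frame_interval,
              x$heart_rate, x$n_phases))
  invisible(x)
}

#' Multi-phase cine image sequence
#'
#' A rank-3 intensity array `[T, H, W]` (phase, row, column) with its
#' acquisition metadata. Intensities may be raw scanner units or normalized.
#'
#' @param frames numeric array `[T, H, W]`.
#' @param meta an [acquisition_meta()].
#' @return An object of class `cine_sequence` with elements `frames`, `meta`.
#' @export
cine_sequence <- function(frames, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  frames <- check_stack(frames, "frames")
  if (dim(frames)[1] != meta$n_phases)
    stop("number of frames must equal meta$n_phases", call. = FALSE)
  structure(list(frames = frames, meta = meta), class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> %d phases of %d x %d\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Per-pixel in-plane velocity field
#'
#' Two rank-3 arrays `[T, H, W]` holding the x (column-direction) and y
#' (row-direction) velocity components in cm/s.
#'
#' @param vx,vy numeric arrays `[T, H, W]`, cm/s.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(vx, vy) {
  vx <- check_stack(vx, "vx"); vy <- check_stack(vy, "vy")
  if (!identical(dim(vx), dim(vy)))
    stop("vx and vy must have identical dimensions", call. = FALSE)
  structure(list(vx = vx, vy = vy), class = "flow_field")
}

#' Per-pixel displacement field
#'
#' Like [flow_field()], but in pixel units per inter-frame interval: `dx`
#' along columns, `dy` along rows.
#'
#' @param dx,dy numeric arrays `[T, H, W]`, pixels per frame interval.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(dx, dy) {
  dx <- check_stack(dx, "dx"); dy <- check_stack(dy, "dy")
  if (!identical(dim(dx), dim(dy)))
    stop("dx and dy must have identical dimensions", call. = FALSE)
  structure(list(dx = dx, dy = dy), class = "displacement_field")
}

#' Labelled blood-pool mask
#'
#' Integer array `[T, H, W]`; 0 = background, chamber labels 1..4 for
#' LV, LA, RV, RA. The nonzero pixels define the set over which losses and
#' metrics are evaluated.
#'
#' @param labels integer array `[T, H, W]` with values in 0..4.
#' @return An object of class `blood_pool_mask`.
#' @export
blood_pool_mask <- function(labels) {
  labels <- check_stack(labels, "labels")
  if (any(labels != round(labels)) || any(labels < 0) || any(labels > 4))
    stop("labels must be integers in 0..4", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "blood_pool_mask")
}

#' Chamber contour set
#'
#' Closed polylines in pixel coordinates, one per phase and chamber, stored as
#' a data frame with columns `phase`, `chamber`, `vertex`, `row`, `col`
#' (0-based phase, integer chamber label, 1-based vertex order). For the LV
#' the first and last vertices are the mitral valve hinge points; the implied
#' closing edge is the valve-plane chord.
#'
#' @param df data frame with columns `phase`, `chamber`, `vertex`, `row`, `col`.
#' @return An object of class `contour_set` (a tibble).
#' @export
contour_set <- function(df) {
  need <- c("phase", "chamber", "vertex", "row", "col")
  if (!all(need %in% names(df)))
    stop("contour data frame needs columns ", paste(need, collapse = ", "), call. = FALSE)
  df <- tibble::as_tibble(df[need])
  if (nrow(df) > 0) {
    cnt <- stats::aggregate(vertex ~ phase + chamber, data = df, FUN = length)
    if (any(cnt$vertex < 3))
      stop("each contour needs at least 3 vertices", call. = FALSE)
  }
  class(df) <- c("contour_set", class(df))
  df
}

# shared validation for [T,H,W] array payloads
check_stack <- function(a, name) {
  if (is.matrix(a)) a <- array(a, c(1L, dim(a)))
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(name, " must be a rank-3 [T,H,W] array", call. = FALSE)
  if (!all(is.finite(a)))
    stop(name, " must be finite everywhere", call. = FALSE)
  storage.mode(a) <- "double"
  a
}

#' Extract one contour as a vertex matrix
#'
#' @param contours a [contour_set()].
#' @param phase 0-based phase index.
#' @param chamber chamber label (1 = LV, 2 = LA, 3 = RV, 4 = RA).
#' @return A two-column matrix `(row, col)` ordered by vertex, or `NULL` if
#'   that contour is absent.
#' @export
contour_vertices <- function(contours, phase, chamber) {
  sub <- contours[contours$phase == phase & contours$chamber == chamber, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  sub <- sub[order(sub$vertex), , drop = FALSE]
  cbind(row = sub$row, col = sub$col)
}
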