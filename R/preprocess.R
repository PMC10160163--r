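#' Normalize cine intensities over the pooled blood-pool histogram
#'
#' Every pixel of every phase is mapped by
#' `(P - P5) / (P95 - P5)`, where `P5` and `P95` are the 5th and 95th
#' percentiles of the intensity histogram built by pooling the blood-pool
#' pixels of *all* cardiac phases. Values outside `[0, 1]` are deliberately
#' not clipped, so flow-induced signal loss remains visible to the network.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param seq a [cine_sequence()].
#' @param mask a [blood_pool_mask()] of the same shape.
#' @return A list with the normalized `cine_sequence` (`cine`) and the
#'   `stats` (list with `p5`, `p95`).
#' @export
normalize_intensities <- function(seq, mask) {
  stopifnot(inherits(seq, "cine_sequence"), inherits(mask, "blood_pool_mask"))
  if (!identical(dim(mask$labels), dim(seq$frames)))
    stop("mask and cine shapes disagree", call. = FALSE)
  pooled <- seq$frames[mask$labels > 0L]
  if (length(pooled) == 0L) stop("mask is empty", call. = FALSE)
  qs <- stats::quantile(pooled, c(0.05, 0.95), names = FALSE, type = 7)
  p5 <- qs[1]; p95 <- qs[2]
  if (p95 <= p5)
    stop("degenerate input: masked intensities have no spread (p95 <= p5)", call. = FALSE)
  norm <- (seq$frames - p5) / (p95 - p5)
  list(cine = cine_sequence(norm, seq$meta), stats = list(p5 = p5, p95 = p95))
}

#' Convert a velocity field to pixel displacements
#'
#' Applies `D = (dt * vx / ps_x, dt * vy / ps_y)` per pixel, with the
#' velocity (cm/s) converted to mm/s so units cancel against the mm pixel
#' spacing. The result is the displacement, in pixels, from frame `t` to
#' frame `t + 1`.
#'
#' @param flow a [flow_field()] in cm/s.
#' @param meta an [acquisition_meta()].
#' @return A [displacement_field()] in pixels per frame interval.
#' @export
velocity_to_displacement <- function(flow, meta) {
  stopifnot(inherits(flow, "flow_field"), inherits(meta, "acquisition_meta"))
  dt <- meta$frame_interval
  displacement_field(dx = dt * (10 * flow$vx) / meta$pixel_spacing[1],
                     dy = dt * (10 * flow$vy) / meta$pixel_spacing[2])
}

#' Convert pixel displacements back to a velocity field
#'
#' Exact inverse of [velocity_to_displacement()]: the per-frame pixel
#' displacement is divided by the temporal resolution and rescaled to cm/s.
#'
#' @param disp a [displacement_field()].
#' @param meta an [acquisition_meta()].
#' @return A [flow_field()] in cm/s.
#' @export
displacement_to_velocity <- function(disp, meta) {
  stopifnot(inherits(disp, "displacement_field"), inherits(meta, "acquisition_meta"))
  dt <- meta$frame_interval
  flow_field(vx = disp$dx * meta$pixel_spacing[1] / dt / 10,
             vy = disp$dy * meta$pixel_spacing[2] / dt / 10)
}

#' Heart-rate consistency check between cine and 4D-flow acquisitions
#'
#' A cine acquisition is excluded when its heart rate deviates from that of
#' the 4D-flow acquisition by more than six beats per minute (strictly more),
#' to avoid temporal inconsistency between the two series.
#'
#' @param hr_cine,hr_flow heart rates in bpm.
#' @param tolerance_bpm exclusion threshold, default 6 bpm.
#' @return `"keep"` or `"exclude"`.
#' @export
check_heart_rate <- function(hr_cine, hr_flow, tolerance_bpm = 6) {
  stopifnot(hr_cine > 0, hr_flow > 0)
  if (abs(hr_cine - hr_flow) > tolerance_bpm) "exclude" else "keep"
}

#' Heart-rate exclusion report for a set of cases
#'
#' @param cases data frame with columns `case_id`, `hr_cine`, `hr_flow`.
#' @param tolerance_bpm exclusion threshold, default 6 bpm.
#' @param file optional CSV path to write the report to.
#' @return A tibble `(case_id, hr_cine, hr_flow, decision)`.
#' @export
heart_rate_report <- function(cases, tolerance_bpm = 6, file = NULL) {
  decision <- mapply(check_heart_rate, cases$hr_cine, cases$hr_flow,
                     MoreArgs = list(tolerance_bpm = tolerance_bpm))
  out <- tibble::tibble(case_id = cases$case_id, hr_cine = cases$hr_cine,
                        hr_flow = cases$hr_flow, decision = decision)
  if (!is.null(file)) utils::write.csv(as.data.frame(out), file, row.names = FALSE)
  out
}

#' Plane geometry for velocity projection
#'
#' Describes a 2D imaging plane embedded in the scanner coordinate system:
#' an origin (the world position of pixel `(0, 0)`), two orthonormal in-plane
#' axes, the pixel spacing along each axis and the plane extent.
#'
#' @param origin world coordinate (mm) of pixel `(row = 0, col = 0)`.
#' @param e_x,e_y unit 3-vectors of the column and row directions.
#' @param spacing `(ps_x, ps_y)` mm per pixel along `e_x` / `e_y`.
#' @param extent `(H, W)` pixels.
#' @return An object of class `plane_geometry`.
#' @export
plane_geometry <- function(origin, e_x, e_y, spacing, extent) {
  e_x <- as.numeric(e_x); e_y <- as.numeric(e_y)
  if (abs(sum(e_x * e_y)) > 1e-8) stop("plane axes must be orthogonal", call. = FALSE)
  if (abs(sqrt(sum(e_x^2)) - 1) > 1e-8 || abs(sqrt(sum(e_y^2)) - 1) > 1e-8)
    stop("plane axes must be unit length", call. = FALSE)
  structure(list(origin = as.numeric(origin), e_x = e_x, e_y = e_y,
                 spacing = as.numeric(spacing), extent = as.integer(extent)),
            class = "plane_geometry")
}

#' Project a volumetric velocity field onto an imaging plane
#'
#' For every plane pixel, the 3-vector velocity is sampled from the regular
#' volume grid by trilinear interpolation at the pixel's world coordinate and
#' projected onto the in-plane axes (`v_x = v . e_x`, `v_y = v . e_y`); the
#' through-plane component is discarded. Pixels falling outside the volume
#' are set to zero and counted.
#'
#' @param vol rank-4 array `[X, Y, Z, 3]`: velocity components on a regular
#'   grid, in cm/s.
#' @param grid_origin world coordinate (mm) of grid node `(1, 1, 1)`.
#' @param grid_spacing `(sx, sy, sz)` mm between grid nodes.
#' @param plane a [plane_geometry()].
#' @return A list: `vx`, `vy` (matrices `[H, W]`, cm/s) and
#'   `n_out_of_bounds`.
#' @export
project_volume_velocity <- function(vol, grid_origin, grid_spacing, plane) {
  stopifnot(length(dim(vol)) == 4L, dim(vol)[4] == 3L)
  H <- plane$extent[1]; W <- plane$extent[2]
  px <- expand.grid(row = 0:(H - 1), col = 0:(W - 1))
  # world coordinate of every pixel center
  world <- outer(rep(1, nrow(px)), plane$origin) +
    outer(px$col * plane$spacing[1], plane$e_x) +
    outer(px$row * plane$spacing[2], plane$e_y)
  # continuous (0-based) grid coordinates
  g <- sweep(sweep(world, 2, grid_origin, "-"), 2, grid_spacing, "/")
  nd <- dim(vol)[1:3]
  oob <- g[, 1] < 0 | g[, 1] > nd[1] - 1 |
         g[, 2] < 0 | g[, 2] > nd[2] - 1 |
         g[, 3] < 0 | g[, 3] > nd[3] - 1
  v <- matrix(0, nrow(px), 3)
  if (any(!oob)) {
    gi <- g[!oob, , drop = FALSE]
    i0 <- pmin(floor(gi[, 1]), nd[1] - 2); j0 <- pmin(floor(gi[, 2]), nd[2] - 2)
    k0 <- pmin(floor(gi[, 3]), nd[3] - 2)
    i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
    fx <- gi[, 1] - i0; fy <- gi[, 2] - j0; fz <- gi[, 3] - k0
    acc <- matrix(0, nrow(gi), 3)
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di == 1) fx else 1 - fx) *
           (if (dj == 1) fy else 1 - fy) *
           (if (dk == 1) fz else 1 - fz)
      idx <- cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)
      for (comp in 1:3)
        acc[, comp] <- acc[, comp] + w * vol[cbind(idx, comp)]
    }
    v[!oob, ] <- acc
  }
  vx <- matrix(v %*% plane$e_x, H, W)
  vy <- matrix(v %*% plane$e_y, H, W)
  list(vx = vx, vy = vy, n_out_of_bounds = sum(oob))
}
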