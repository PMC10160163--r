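#' Rasterize chamber contours to a labelled mask
#'
#' Converts closed chamber polygons to a per-phase labelled blood-pool mask.
#' A pixel is labelled `c` iff its center (integer `(row, col)` coordinate)
#' lies inside the chamber-`c` polygon under the even-odd rule. Where
#' chambers overlap, the lowest chamber index wins.
#'
#' @param contours a [contour_set()].
#' @param shape `(H, W)` of the target grid.
#' @param n_phases number of phases of the output mask; defaults to
#'   `max(contours$phase) + 1`.
#' @return A [blood_pool_mask()] of dimension `[n_phases, H, W]`.
#' @export
rasterize_contours <- function(contours, shape, n_phases = NULL) {
  H <- shape[1]; W <- shape[2]
  if (is.null(n_phases)) {
    n_phases <- if (nrow(contours) > 0) max(contours$phase) + 1L else 1L
  }
  labels <- array(0L, c(n_phases, H, W))
  if (nrow(contours) > 0) {
    if (any(contours$row < 0 | contours$row > H - 1 |
            contours$col < 0 | contours$col > W - 1))
      stop("contour coordinates outside image bounds", call. = FALSE)
    px <- as.matrix(expand.grid(row = 0:(H - 1), col = 0:(W - 1)))
    for (ph in sort(unique(contours$phase))) {
      chams <- sort(unique(contours$chamber[contours$phase == ph]), decreasing = TRUE)
      for (ch in chams) {  # decreasing so the lowest label overwrites last
        poly <- contour_vertices(contours, ph, ch)
        if (nrow(poly) < 3) stop("degenerate contour (<3 vertices)", call. = FALSE)
        inside <- points_in_polygon(px[, "row"], px[, "col"], poly[, 1], poly[, 2])
        plane <- labels[ph + 1L, , ]
        plane[matrix(inside, H, W)] <- as.integer(ch)
        labels[ph + 1L, , ] <- plane
      }
    }
  }
  blood_pool_mask(labels)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Edges are taken between consecutive vertices and from the last back to the
# first. Points lying exactly on a polygon edge count as inside.
points_in_polygon <- function(pr, pc, vr, vc, eps = 1e-9) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  boundary <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vr[i]; yj <- vr[j]; xi <- vc[i]; xj <- vc[j]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment test for edge (j -> i)
    ey <- yi - yj; ex <- xi - xj
    len2 <- ey * ey + ex * ex
    if (len2 > 0) {
      cross <- (pr - yj) * ex - (pc - xj) * ey
      dot <- (pr - yj) * ey + (pc - xj) * ex
      boundary <- boundary |
        (abs(cross) <= eps * sqrt(len2) & dot >= -eps & dot <= len2 + eps)
    }
    j <- i
  }
  inside | boundary
}

#' Extract a cyclic temporal window of frames
#'
#' Returns the sub-stack of `2k + 1` frames centered on phase `t`. The
#' cardiac cycle is periodic, so indices wrap around the `T` phases; the
#' central frame sits at (1-based) position `k + 1` of the result.
#'
#' @param seq a [cine_sequence()] or a plain `[T, H, W]` array.
#' @param t 0-based central phase index.
#' @param k window half-width (`k = 4` gives the 9-frame input of the
#'   default network: the target frame plus its 8 temporal neighbours).
#' @param k_after phases taken after `t`; defaults to `k`, so the window is
#'   symmetric unless an asymmetric split is requested explicitly.
#' @return An array `[k + k_after + 1, H, W]` with the target frame at
#'   (1-based) position `k + 1`.
#' @export
temporal_window <- function(seq, t, k, k_after = k) {
  frames <- if (inherits(seq, "cine_sequence")) seq$frames else seq
  T_ <- dim(frames)[1]
  if (k < 0 || k_after < 0 || k + k_after + 1 > T_)
    stop("window half-widths must satisfy 0 <= k, k_after and k + k_after + 1 <= T",
         call. = FALSE)
  if (t < 0 || t >= T_) stop("phase index out of range", call. = FALSE)
  idx <- ((t - k):(t + k_after)) %% T_ + 1L
  frames[idx, , , drop = FALSE]
}

#' Translate an image or flow stack in-plane
#'
#' Shifts every phase of the stack by an integer `(rows, cols)` offset,
#' zero-filling vacated pixels. Used to reproduce the manual in-plane
#' alignment between cine images and projected 4D-flow velocities as a
#' programmatic operator.
#'
#' @param x a [cine_sequence()], [flow_field()] or `[T, H, W]` array.
#' @param offset integer `(delta_row, delta_col)`; positive moves content
#'   down/right.
#' @return Same type as `x`.
#' @export
translate_inplane <- function(x, offset) {
  offset <- as.integer(round(offset))
  if (inherits(x, "cine_sequence"))
    return(cine_sequence(shift_stack(x$frames, offset), x$meta))
  if (inherits(x, "flow_field"))
    return(flow_field(shift_stack(x$vx, offset), shift_stack(x$vy, offset)))
  shift_stack(x, offset)
}

shift_stack <- function(a, offset) {
  d <- dim(a); H <- d[2]; W <- d[3]
  dr <- offset[1]; dc <- offset[2]
  if (abs(dr) >= H || abs(dc) >= W)
    stop("offset magnitude must be smaller than the image extent", call. = FALSE)
  out <- array(0, d)
  src_r <- max(1, 1 - dr):min(H, H - dr)
  src_c <- max(1, 1 - dc):min(W, W - dc)
  out[, src_r + dr, src_c + dc] <- a[, src_r, src_c, drop = FALSE]
  out
}
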