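#' Mitral-valve region of interest from the LV contour
#'
#' The ROI is bounded by the valve-plane chord between the two hinge points
#' (the first and last vertices of the LV endocardial contour) and a
#' quadratic b-spline curve passed through three points — the two hinge
#' points and a point in the center of the LV cavity — giving a region just
#' below the mitral valve plane. The returned pixels are those enclosed
#' between chord and curve, intersected with the LV mask.
#'
#' @param lv_poly LV contour vertex matrix `(row, col)`; first and last rows
#'   are the hinge points.
#' @param cavity_center `(row, col)` of the LV cavity center.
#' @param shape `(H, W)`.
#' @param lv_mask optional logical/integer `[H, W]` LV mask to intersect
#'   with.
#' @return Logical matrix `[H, W]`; attribute `degenerate` is `TRUE` when
#'   the three points are (near) collinear and the ROI collapses onto the
#'   chord.
#' @export
mitral_roi <- function(lv_poly, cavity_center, shape, lv_mask = NULL) {
  h1 <- lv_poly[1, ]; h2 <- lv_poly[nrow(lv_poly), ]
  chord <- h2 - h1
  rel <- cavity_center - h1
  area2 <- chord[1] * rel[2] - chord[2] * rel[1]    # twice the triangle area
  degenerate <- abs(area2) < 0.5 * sqrt(sum(chord^2))
  if (degenerate) {
    warning("hinge points and cavity center are (near) collinear; ROI degenerates to the chord")
    roi <- matrix(FALSE, shape[1], shape[2])
    attr(roi, "degenerate") <- TRUE
    return(roi)
  }
  # quadratic curve through (h1, center, h2): Bezier with control point
  # chosen so the curve interpolates the cavity center at s = 1/2
  ctrl <- 2 * cavity_center - (h1 + h2) / 2
  s <- seq(0, 1, length.out = 100)
  curve <- outer((1 - s)^2, h1) + outer(2 * s * (1 - s), ctrl) + outer(s^2, h2)
  poly_r <- c(curve[, 1], h1[1])
  poly_c <- c(curve[, 2], h1[2])
  px <- expand.grid(row = 0:(shape[1] - 1), col = 0:(shape[2] - 1))
  inside <- points_in_polygon(px$row, px$col, poly_r, poly_c)
  roi <- matrix(inside, shape[1], shape[2])
  if (!is.null(lv_mask)) roi <- roi & (lv_mask > 0)
  attr(roi, "degenerate") <- FALSE
  roi
}

#' Per-phase mitral ROI stack for a case
#'
#' Builds the ROI of [mitral_roi()] for every phase, taking the cavity
#' center as the centroid of the LV-labelled pixels of that phase.
#'
#' @param contours a [contour_set()] with LV contours (chamber 1).
#' @param mask a [blood_pool_mask()].
#' @return Logical array `[T, H, W]`.
#' @export
mitral_roi_stack <- function(contours, mask) {
  d <- dim(mask$labels); T_ <- d[1]
  roi <- array(FALSE, d)
  for (t in 0:(T_ - 1)) {
    poly <- contour_vertices(contours, t, 1L)
    if (is.null(poly)) next
    lv <- mask$labels[t + 1, , ] == 1L
    if (!any(lv)) next
    idx <- which(lv, arr.ind = TRUE)
    center <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)   # 0-based centroid
    roi[t + 1, , ] <- mitral_roi(poly, center, d[2:3], lv_mask = lv)
  }
  roi
}

#' Maximum in-plane speed within an ROI over the cycle
#'
#' @param flow a [flow_field()] (cm/s).
#' @param roi logical `[T, H, W]` array, or a single `[H, W]` matrix reused
#'   for every phase.
#' @return Numeric length-`T` series; `NA` where the ROI is empty.
#' @export
max_velocity_curve <- function(flow, roi) {
  T_ <- dim(flow$vx)[1]
  if (is.matrix(roi)) roi <- array(rep(roi, each = T_), c(T_, dim(roi)))
  vapply(seq_len(T_), function(t) {
    m <- roi[t, , ]
    if (!any(m)) return(NA_real_)
    max(sqrt(flow$vx[t, , ][m]^2 + flow$vy[t, , ][m]^2))
  }, numeric(1))
}

# interior local maxima of a series (strict rise, non-strict fall)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect E and A peaks on a transmitral velocity curve
#'
#' Works on the diastolic segment of the per-phase maximum-velocity curve.
#' When `systole_end_phase` is not given, diastole onset is estimated as the
#' first local minimum after the first local maximum (the systolic peak) of
#' the curve. Within diastole, local maxima with prominence of at least
#' `prominence_frac` of the diastolic range are retained; E is the first
#' such peak and A the last. Fewer than two prominent peaks is an explicit
#' failure, never a silent `NaN` ratio.
#'
#' @param curve length-`T` numeric series (cm/s), possibly with `NA`s.
#' @param systole_end_phase optional 0-based phase index where diastole
#'   starts.
#' @param prominence_frac fraction of the diastolic range a peak must rise
#'   above the segment minimum.
#' @return A list: `status` (`"ok"`/`"failed"`), and for `"ok"`
#'   `e_velocity`, `a_velocity`, `ratio`, `e_phase`, `a_phase` (0-based),
#'   `diastole_start`; for `"failed"` a `reason`.
#' @export
detect_e_a <- function(curve, systole_end_phase = NULL, prominence_frac = 0.1) {
  T_ <- length(curve)
  if (is.null(systole_end_phase)) {
    lm <- local_maxima(curve)
    if (length(lm) == 0L)
      return(list(status = "failed", reason = "no systolic peak found"))
    sys_peak <- lm[1]
    seg <- curve[sys_peak:T_]
    mins <- which(seg[2:(length(seg) - 1)] < seg[1:(length(seg) - 2)] &
                  seg[2:(length(seg) - 1)] <= seg[3:length(seg)]) + 1L
    if (length(mins) == 0L)
      return(list(status = "failed", reason = "no diastole onset found"))
    d0 <- sys_peak + mins[1] - 1L
  } else {
    d0 <- systole_end_phase + 1L
    if (d0 < 1L || d0 > T_ - 2L)
      return(list(status = "failed", reason = "invalid diastole onset"))
  }
  dia <- curve[d0:T_]
  if (any(is.na(dia)))
    return(list(status = "failed", reason = "missing values in diastolic segment"))
  rng <- max(dia) - min(dia)
  if (rng <= 0)
    return(list(status = "failed", reason = "flat diastolic curve"))
  peaks <- local_maxima(dia)
  peaks <- peaks[dia[peaks] - min(dia) >= prominence_frac * rng]
  if (length(peaks) < 2L)
    return(list(status = "failed",
                reason = "fewer than two prominent diastolic peaks"))
  e_i <- peaks[1]; a_i <- peaks[length(peaks)]
  list(status = "ok",
       e_velocity = dia[e_i], a_velocity = dia[a_i],
       ratio = dia[e_i] / dia[a_i],
       e_phase = d0 + e_i - 2L, a_phase = d0 + a_i - 2L,
       diastole_start = d0 - 1L)
}

#' Classify diastolic function from the E/A ratio
#'
#' Normal diastolic function is defined by `0.75 < E/A < 1.5` (strict
#' inequalities, the echocardiographic convention); any other ratio is
#' abnormal.
#'
#' @param ratio E/A ratio, positive.
#' @return `0` (normal) or `1` (abnormal).
#' @export
classify_diastolic <- function(ratio) {
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be positive", call. = FALSE)
  if (ratio > 0.75 && ratio < 1.5) 0L else 1L
}

#' Automated E/A estimation for one case
#'
#' Chains [mitral_roi_stack()], [max_velocity_curve()], [detect_e_a()] and
#' [classify_diastolic()].
#'
#' @param flow a [flow_field()] (predicted or reference), cm/s.
#' @param contours a [contour_set()] with the LV contour.
#' @param mask a [blood_pool_mask()].
#' @param systole_end_phase optional 0-based diastole onset override.
#' @return The [detect_e_a()] result, with `diastolic_class` added when
#'   detection succeeded.
#' @export
ea_from_flow <- function(flow, contours, mask, systole_end_phase = NULL) {
  roi <- mitral_roi_stack(contours, mask)
  curve <- max_velocity_curve(flow, roi)
  res <- detect_e_a(curve, systole_end_phase)
  if (res$status == "ok") res$diastolic_class <- classify_diastolic(res$ratio)
  res$curve <- curve
  res
}

#' Bland-Altman agreement statistics for paired measurements
#'
#' Differences are `pred - ref`; the bias is their mean, the limits of
#' agreement `bias +/- 1.96 * SD` (sample SD), with Pearson correlation of
#' the pairs and a two-sided paired t-test.
#'
#' @param pred,ref numeric vectors of equal length (n >= 2).
#' @return An object of class `agreement_stats`: list with `bias`,
#'   `loa_half_width`, `loa_lower`, `loa_upper`, `pcc`, `t_statistic`,
#'   `p_value`, `n`, `differences`, `means`.
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) < 2L)
    stop("need at least 2 paired measurements", call. = FALSE)
  d <- pred - ref
  bias <- mean(d)
  sdd <- stats::sd(d)
  tt <- stats::t.test(pred, ref, paired = TRUE)
  structure(list(bias = bias, loa_half_width = 1.96 * sdd,
                 loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
                 pcc = stats::cor(pred, ref),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 n = length(d), differences = d, means = (pred + ref) / 2),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d, bias = %.4g, LOA = [%.4g, %.4g], PCC = %.3f, t = %.3f, p = %.3g\n",
              x$n, x$bias, x$loa_lower, x$loa_upper, x$pcc, x$t_statistic, x$p_value))
  invisible(x)
}

#' One-row summary of an agreement analysis
#' @param x an `agreement_stats`.
#' @return A tibble with the agreement statistics.
#' @export
glance_agreement <- function(x) {
  tibble::tibble(n = x$n, bias = x$bias, loa_half_width = x$loa_half_width,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 pcc = x$pcc, t_statistic = x$t_statistic, p_value = x$p_value)
}

#' Binary confusion metrics for diastolic-function classification
#'
#' Reference labels index the rows of the 2x2 count matrix, predictions the
#' columns (label 0 = normal, 1 = abnormal). Per class, precision is
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 their harmonic mean; a
#' class absent from both vectors gets `NA` metrics.
#'
#' @param ref_labels,pred_labels equal-length vectors of 0/1 labels.
#' @return An object of class `confusion_metrics`: list with `counts` (2x2
#'   matrix), `accuracy`, `per_class` (tibble).
#' @export
confusion_metrics <- function(ref_labels, pred_labels) {
  stopifnot(length(ref_labels) == length(pred_labels))
  if (!all(c(ref_labels, pred_labels) %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  lv <- c(0, 1)
  counts <- table(factor(ref_labels, levels = lv), factor(pred_labels, levels = lv))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(ref = c("normal", "abnormal"),
                                   pred = c("normal", "abnormal")))
  n <- sum(counts)
  per_class <- do.call(rbind, lapply(1:2, function(i) {
    cls <- c("normal", "abnormal")[i]
    tp <- counts[i, i]
    fp <- sum(counts[-i, i])
    fn <- sum(counts[i, -i])
    if (tp + fp + fn == 0L)
      return(tibble::tibble(class = cls, precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_))
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    tibble::tibble(class = cls, precision = precision, recall = recall, f1 = f1)
  }))
  structure(list(counts = counts, accuracy = sum(diag(counts)) / n,
                 per_class = per_class, n = n),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  print(x$counts)
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' Confusion metrics from a printed 2x2 count matrix
#'
#' Convenience wrapper expanding a count matrix (rows = reference
#' normal/abnormal, columns = predicted) into label vectors.
#'
#' @param counts 2x2 integer matrix.
#' @return A [confusion_metrics()] object.
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L))
  ref <- c(rep(0, counts[1, 1] + counts[1, 2]), rep(1, counts[2, 1] + counts[2, 2]))
  pred <- c(rep(0, counts[1, 1]), rep(1, counts[1, 2]),
            rep(0, counts[2, 1]), rep(1, counts[2, 2]))
  confusion_metrics(ref, pred)
}
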