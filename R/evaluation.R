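speed_of <- function(flow) sqrt(flow$vx^2 + flow$vy^2)

qualifying <- function(ref, mask, vmin) (mask$labels > 0L) & (speed_of(ref) > vmin)

#' End-point error on velocity fields
#'
#' Masked EPE applied to velocity vectors, pooled over all phases. Only
#' pixels whose *reference* speed exceeds `vmin` participate — evaluation
#' conditions on the true flow regime, so noise-level reference pixels do
#' not dominate.
#'
#' @param pred,ref [flow_field()]s in cm/s.
#' @param mask a [blood_pool_mask()].
#' @param vmin reference-speed gate in cm/s (default 5; strictly greater).
#' @return Scalar EPE in cm/s.
#' @export
velocity_epe <- function(pred, ref, mask, vmin = 5) {
  q <- qualifying(ref, mask, vmin)
  if (!any(q)) stop("degenerate input: no pixels qualify above vmin", call. = FALSE)
  mean(sqrt((pred$vx[q] - ref$vx[q])^2 + (pred$vy[q] - ref$vy[q])^2))
}

#' Mean angular error between velocity fields
#'
#' Mean over qualifying pixels of
#' `arccos( (Vp . Vg) / (|Vp| |Vg|) )` in degrees; 0 means parallel, 180
#' opposite. The cosine is clamped into `[-1, 1]` before `acos`. Pixels
#' where either vector has zero magnitude are excluded; their count is
#' attached as attribute `n_zero_excluded`.
#'
#' @inheritParams velocity_epe
#' @return Mean angle error in degrees, in `[0, 180]`.
#' @export
angle_error <- function(pred, ref, mask, vmin = 5) {
  q <- qualifying(ref, mask, vmin)
  if (!any(q)) stop("degenerate input: no pixels qualify above vmin", call. = FALSE)
  px <- pred$vx[q]; py <- pred$vy[q]
  gx <- ref$vx[q]; gy <- ref$vy[q]
  np <- sqrt(px^2 + py^2); ng <- sqrt(gx^2 + gy^2)
  nz <- np > 0 & ng > 0
  if (!any(nz)) stop("degenerate input: all qualifying vectors have zero magnitude",
                     call. = FALSE)
  cosang <- pmin(1, pmax(-1, (px[nz] * gx[nz] + py[nz] * gy[nz]) / (np[nz] * ng[nz])))
  out <- mean(acos(cosang)) * 180 / pi
  attr(out, "n_zero_excluded") <- sum(!nz)
  out
}

#' Signed relative error of mean velocity magnitude
#'
#' `100 * (mean|Vp| - mean|Vg|) / mean|Vg|` over all masked pixels and
#' phases; negative values indicate underestimation by the prediction.
#'
#' @inheritParams velocity_epe
#' @return Signed relative error in percent.
#' @export
relative_error <- function(pred, ref, mask) {
  m <- mask$labels > 0L
  if (!any(m)) stop("degenerate input: empty mask", call. = FALSE)
  mp <- mean(sqrt(pred$vx[m]^2 + pred$vy[m]^2))
  mg <- mean(sqrt(ref$vx[m]^2 + ref$vy[m]^2))
  if (mg == 0) stop("degenerate input: reference speed is zero in mask", call. = FALSE)
  100 * (mp - mg) / mg
}

#' Pearson correlation of the velocity time curves
#'
#' Correlates the two length-`T` series of spatially averaged masked speed
#' per cardiac phase.
#'
#' @inheritParams velocity_epe
#' @return Pearson r, or `NA` (with a warning) when a series has zero
#'   variance.
#' @export
velocity_pcc <- function(pred, ref, mask) {
  T_ <- dim(ref$vx)[1]
  if (T_ < 3L) stop("need at least 3 phases", call. = FALSE)
  series <- function(flow) vapply(seq_len(T_), function(t) {
    m <- mask$labels[t, , ] > 0L
    mean(sqrt(flow$vx[t, , ][m]^2 + flow$vy[t, , ][m]^2))
  }, numeric(1))
  sp <- series(pred); sg <- series(ref)
  if (stats::sd(sp) == 0 || stats::sd(sg) == 0) {
    warning("zero-variance velocity series; PCC undefined")
    return(NA_real_)
  }
  stats::cor(sp, sg)
}

#' Velocity magnitude histogram
#'
#' Probability distribution of masked speeds across all phases over the given
#' bin edges; out-of-range speeds are accumulated into the end bins.
#'
#' @param flow a [flow_field()].
#' @param mask a [blood_pool_mask()].
#' @param edges monotone increasing bin edges, cm/s.
#' @return A tibble `(lower, upper, mass)` of class `velocity_histogram`;
#'   `mass` sums to 1.
#' @export
velocity_histogram <- function(flow, mask, edges = seq(0, 50, by = 2)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing", call. = FALSE)
  m <- mask$labels > 0L
  if (!any(m)) stop("degenerate input: empty mask", call. = FALSE)
  sp <- speed_of(flow)[m]
  nb <- length(edges) - 1L
  sp <- pmin(pmax(sp, edges[1]), edges[length(edges)])
  bin <- pmin(pmax(findInterval(sp, edges, rightmost.closed = TRUE), 1L), nb)
  mass <- tabulate(bin, nb) / length(sp)
  out <- tibble::tibble(lower = edges[-length(edges)], upper = edges[-1], mass = mass)
  class(out) <- c("velocity_histogram", class(out))
  out
}

#' Metrics at a series of reference-speed thresholds
#'
#' Recomputes EPE and angle error at each gate in `vmins`, together with the
#' number of qualifying pixels (non-increasing in the threshold); rows with
#' no qualifying pixels carry `NA` metrics.
#'
#' @inheritParams velocity_epe
#' @param vmins numeric vector of thresholds, cm/s.
#' @return A tibble `(vmin, n_pixels, epe, angle_error)`.
#' @export
threshold_sweep <- function(pred, ref, mask, vmins = c(0, 2.5, 5, 7.5, 10, 15, 20)) {
  stopifnot(length(vmins) >= 1L)
  rows <- lapply(vmins, function(v) {
    n <- sum(qualifying(ref, mask, v))
    if (n == 0L)
      return(tibble::tibble(vmin = v, n_pixels = 0L, epe = NA_real_,
                            angle_error = NA_real_))
    tibble::tibble(vmin = v, n_pixels = n,
                   epe = velocity_epe(pred, ref, mask, v),
                   angle_error = as.numeric(angle_error(pred, ref, mask, v)))
  })
  do.call(rbind, rows)
}

#' Fraction of qualifying pixels with EPE below a reference-speed percentile
#'
#' An accuracy-style summary whose published definition is ambiguous; the
#' reading implemented here is: among masked pixels whose reference speed
#' exceeds `vmin`, the fraction whose per-pixel velocity EPE falls below the
#' given percentile of the qualifying reference speeds. It is not part of
#' [evaluate_regions()] output and must be requested explicitly.
#'
#' @inheritParams velocity_epe
#' @param percentile percentile of the qualifying reference-speed
#'   distribution used as the per-pixel error bound (default 0.30).
#' @return Fraction in `[0, 1]`.
#' @export
gated_accuracy <- function(pred, ref, mask, vmin = 5, percentile = 0.30) {
  q <- qualifying(ref, mask, vmin)
  if (!any(q)) stop("degenerate input: no pixels qualify above vmin", call. = FALSE)
  ref_speed <- speed_of(ref)[q]
  bound <- stats::quantile(ref_speed, percentile, names = FALSE, type = 7)
  epe_px <- sqrt((pred$vx[q] - ref$vx[q])^2 + (pred$vy[q] - ref$vy[q])^2)
  mean(epe_px < bound)
}

chamber_names <- c("LV", "LA", "RV", "RA")

restrict_mask <- function(mask, label) {
  lab <- mask$labels
  lab[lab != label] <- 0L
  blood_pool_mask(lab)
}

#' Per-region evaluation of one case
#'
#' Computes velocity EPE, angle error, relative error and time-curve PCC for
#' the all-chamber aggregate (`4CH`, all labelled pixels) and for every
#' chamber label present in the mask.
#'
#' @inheritParams velocity_epe
#' @return A tibble `(region, n_pixels, epe, angle_error, relative_error,
#'   pcc)`.
#' @export
evaluate_regions <- function(pred, ref, mask, vmin = 5) {
  labels_present <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  regions <- c(list(list(name = "4CH", mask = mask)),
               lapply(labels_present, function(l)
                 list(name = chamber_names[l], mask = restrict_mask(mask, l))))
  rows <- lapply(regions, function(rg) {
    met <- function(f) tryCatch(as.numeric(f), error = function(e) NA_real_)
    tibble::tibble(
      region = rg$name,
      n_pixels = sum(rg$mask$labels > 0L),
      epe = met(velocity_epe(pred, ref, rg$mask, vmin)),
      angle_error = met(angle_error(pred, ref, rg$mask, vmin)),
      relative_error = met(relative_error(pred, ref, rg$mask)),
      pcc = met(suppressWarnings(velocity_pcc(pred, ref, rg$mask))))
  })
  do.call(rbind, rows)
}

#' Cohort summary of per-case region metrics
#'
#' Case-level means are averaged across cases (never pixel-pooled) and
#' reported as mean and standard deviation per region and metric.
#'
#' @param case_tables list of tibbles from [evaluate_regions()].
#' @return A tibble `(region, metric, mean, sd, n_cases)`.
#' @export
evaluate_cohort <- function(case_tables) {
  all_ <- do.call(rbind, Map(function(tb, i) {
    tb$case <- i; tb
  }, case_tables, seq_along(case_tables)))
  metrics <- c("epe", "angle_error", "relative_error", "pcc")
  rows <- list()
  for (rg in unique(all_$region)) for (mt in metrics) {
    v <- all_[[mt]][all_$region == rg]
    v <- v[!is.na(v)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      region = rg, metric = mt, mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_, n_cases = length(v))
  }
  do.call(rbind, rows)
}
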