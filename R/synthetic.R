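#' Configuration of a synthetic cine phantom
#'
#' Defines a two-chamber long-axis-like phantom: an elliptical "LV" holding a
#' solid-rotation vortex modulated by a systolic envelope, an elliptical "LA"
#' above it, and a biphasic diastolic inflow jet through a gap on the LV
#' ellipse (the mitral plane) whose speed over the cycle is
#' `g(t) = E exp(-(t - t_E)^2 / 2 s^2) + A exp(-(t - t_A)^2 / 2 s^2)`
#' with `t` the cycle fraction. Intensity frames are produced by advecting a
#' band-limited random texture with the exactly known flow.
#'
#' The default peak timings (`0.6`, `0.9` of the cycle) fall exactly on the
#' 30-phase sampling grid, and the default temporal width `0.05` keeps the
#' two Gaussians well separated (`s < |t_A - t_E| / 4`).
#'
#' @param grid `(H, W)` pixels.
#' @param n_phases phases per cardiac cycle.
#' @param ps pixel spacing mm (scalar or `(ps_x, ps_y)`).
#' @param heart_rate bpm; the frame interval is `60 / (heart_rate * n_phases)`.
#' @param lv_center,lv_semi LV ellipse center `(row, col)` and semi-axes
#'   `(rows, cols)`, pixels.
#' @param la_center,la_semi LA ellipse center and semi-axes, pixels.
#' @param gap_half_angle half-angle (radians) of the mitral gap on the LV
#'   ellipse, measured from its top.
#' @param vortex_peak peak vortex speed, cm/s.
#' @param systole_peak_frac,systole_width systolic envelope Gaussian center
#'   and width (cycle fractions).
#' @param e_peak,a_peak early and atrial jet peak speeds, cm/s.
#' @param e_frac,a_frac cycle fractions of the two jet peaks
#'   (`0 < e_frac < a_frac < 1`).
#' @param jet_sigma temporal Gaussian width of both jet bumps, cycle fraction.
#' @param jet_width,jet_length transverse (Gaussian sigma) and axial decay
#'   lengths of the jet spatial profile, pixels.
#' @param texture_length correlation length of the speckle texture, pixels.
#' @param noise_sd additive Gaussian noise, fraction of the intensity range.
#' @param attenuation_lambda speed-proportional intensity attenuation
#'   `exp(-lambda |v|)`; `0` disables it.
#' @param seed RNG seed for texture and noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(64, 64), n_phases = 30, ps = 3,
                           heart_rate = 60,
                           lv_center = NULL, lv_semi = NULL,
                           la_center = NULL, la_semi = NULL,
                           gap_half_angle = 0.6,
                           vortex_peak = 30,
                           systole_peak_frac = 0.2, systole_width = 0.1,
                           e_peak = 60, a_peak = 40,
                           e_frac = 0.6, a_frac = 0.9, jet_sigma = 0.05,
                           jet_width = 4, jet_length = 10,
                           texture_length = 2, noise_sd = 0.01,
                           attenuation_lambda = 0, seed = 1L) {
  H <- grid[1]; W <- grid[2]
  if (is.null(lv_center)) lv_center <- c(0.63 * H, 0.5 * W)
  if (is.null(lv_semi))   lv_semi   <- c(0.27 * H, 0.20 * W)
  if (is.null(la_center)) la_center <- c(0.20 * H, 0.5 * W)
  if (is.null(la_semi))   la_semi   <- c(0.125 * H, 0.14 * W)
  if (!(e_frac > 0 && e_frac < 1 && a_frac > 0 && a_frac < 1 && e_frac < a_frac))
    stop("peak fractions must lie in (0,1) with e_frac < a_frac", call. = FALSE)
  if (e_peak < 0 || a_peak < 0 || vortex_peak < 0)
    stop("speeds must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (gap_half_angle <= 0 || gap_half_angle >= pi / 2)
    stop("jet gap must lie on the upper LV ellipse (0 < half-angle < pi/2)", call. = FALSE)
  structure(list(
    grid = as.integer(grid), n_phases = as.integer(n_phases),
    ps = if (length(ps) == 1) rep(ps, 2) else as.numeric(ps),
    heart_rate = heart_rate,
    frame_interval = 60 / (heart_rate * n_phases),
    lv_center = lv_center, lv_semi = lv_semi,
    la_center = la_center, la_semi = la_semi,
    gap_half_angle = gap_half_angle,
    vortex_peak = vortex_peak,
    systole_peak_frac = systole_peak_frac, systole_width = systole_width,
    e_peak = e_peak, a_peak = a_peak,
    e_frac = e_frac, a_frac = a_frac, jet_sigma = jet_sigma,
    jet_width = jet_width, jet_length = jet_length,
    texture_length = texture_length, noise_sd = noise_sd,
    attenuation_lambda = attenuation_lambda, seed = as.integer(seed)),
    class = "phantom_config")
}

#' Small-motion phantom configuration
#'
#' The default [phantom_config()] speeds, at 3 mm pixels and 30 phases of a
#' 1 s cycle, give peak displacements of several pixels per frame. For
#' network training experiments a slow-flow variant with the same geometry
#' and timing but all speeds scaled so the peak displacement stays below
#' about 2 px/frame is used.
#'
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_config_smallmotion <- function(...) {
  phantom_config(e_peak = 15, a_peak = 10, vortex_peak = 8, ...)
}

#' Biphasic diastolic jet speed curve
#'
#' @param cfg a [phantom_config()].
#' @param t_frac cycle fractions (vector).
#' @return Jet speed `g(t)` in cm/s.
#' @export
jet_speed_curve <- function(cfg, t_frac) {
  cfg$e_peak * exp(-(t_frac - cfg$e_frac)^2 / (2 * cfg$jet_sigma^2)) +
    cfg$a_peak * exp(-(t_frac - cfg$a_frac)^2 / (2 * cfg$jet_sigma^2))
}

ellipse_inside <- function(H, W, center, semi) {
  r <- matrix(0:(H - 1), H, W)
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c_ - center[2]) / semi[2])^2 <= 1
}

# LV endocardial contour: ellipse boundary from one hinge point around the
# apex to the other; first and last vertices are the valve hinge points.
lv_contour_points <- function(cfg, n = 72) {
  th <- seq(cfg$gap_half_angle, 2 * pi - cfg$gap_half_angle, length.out = n)
  cbind(row = cfg$lv_center[1] - cfg$lv_semi[1] * cos(th),
        col = cfg$lv_center[2] + cfg$lv_semi[2] * sin(th))
}

la_contour_points <- function(cfg, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = cfg$la_center[1] - cfg$la_semi[1] * cos(th),
        col = cfg$la_center[2] + cfg$la_semi[2] * sin(th))
}

#' Generate the exact phantom flow field, mask and contours
#'
#' Inside the LV ellipse: a divergence-free solid-rotation vortex whose speed
#' is scaled by a Gaussian systolic envelope, plus the diastolic inflow jet
#' directed from the LA through the mitral gap into the LV. The LA carries
#' the matching outflow (same jet, upstream side). The field is identically
#' zero outside the labelled blood pool.
#'
#' @param cfg a [phantom_config()].
#' @param components `"all"`, `"vortex"` or `"jet"` — restrict the generated
#'   field to one component (useful for testing conservation properties).
#' @return A list: `flow` ([flow_field()]), `mask` ([blood_pool_mask()]),
#'   `contours` ([contour_set()]), `meta` ([acquisition_meta()]).
#' @export
make_flow_field <- function(cfg, components = c("all", "vortex", "jet")) {
  components <- match.arg(components)
  H <- cfg$grid[1]; W <- cfg$grid[2]; T_ <- cfg$n_phases
  lv <- ellipse_inside(H, W, cfg$lv_center, cfg$lv_semi)
  la <- ellipse_inside(H, W, cfg$la_center, cfg$la_semi)
  la <- la & !lv
  labels1 <- matrix(0L, H, W)
  labels1[la] <- 2L
  labels1[lv] <- 1L
  r <- matrix(0:(H - 1), H, W)
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE)

  # vortex: solid rotation about the LV center, peak speed at the largest
  # in-ellipse radius
  dy_ <- r - cfg$lv_center[1]; dx_ <- c_ - cfg$lv_center[2]
  r_max <- max(cfg$lv_semi)
  omega <- if (cfg$vortex_peak > 0) cfg$vortex_peak / r_max else 0
  vort_vx <- -omega * dy_
  vort_vy <-  omega * dx_
  vort_vx[!lv] <- 0; vort_vy[!lv] <- 0

  # jet geometry: hinge points and gap midpoint on the LV ellipse
  lv_poly <- lv_contour_points(cfg)
  hinges <- lv_poly[c(1L, nrow(lv_poly)), ]
  gap_mid <- colMeans(hinges)
  axis_dir <- cfg$lv_center - cfg$la_center
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))        # (row, col), points into LV
  perp <- c(-axis_dir[2], axis_dir[1])
  a_coord <- (r - gap_mid[1]) * axis_dir[1] + (c_ - gap_mid[2]) * axis_dir[2]
  q_coord <- (r - gap_mid[1]) * perp[1] + (c_ - gap_mid[2]) * perp[2]
  jet_profile <- exp(-q_coord^2 / (2 * cfg$jet_width^2)) *
    exp(-a_coord^2 / (2 * cfg$jet_length^2))
  jet_profile[abs(q_coord) > 3 * cfg$jet_width] <- 0
  jet_profile[labels1 == 0L] <- 0

  t_frac <- (0:(T_ - 1)) / T_
  sys_env <- exp(-(t_frac - cfg$systole_peak_frac)^2 / (2 * cfg$systole_width^2))
  g <- jet_speed_curve(cfg, t_frac)

  vx <- array(0, c(T_, H, W)); vy <- array(0, c(T_, H, W))
  for (t in seq_len(T_)) {
    fx <- 0; fy <- 0
    if (components %in% c("all", "vortex")) {
      fx <- fx + sys_env[t] * vort_vx
      fy <- fy + sys_env[t] * vort_vy
    }
    if (components %in% c("all", "jet")) {
      fx <- fx + g[t] * jet_profile * axis_dir[2]
      fy <- fy + g[t] * jet_profile * axis_dir[1]
    }
    vx[t, , ] <- fx; vy[t, , ] <- fy
  }

  labels <- array(rep(labels1, each = T_), c(T_, H, W))
  lvp <- lv_contour_points(cfg)
  lap <- la_contour_points(cfg)
  cont <- do.call(rbind, lapply(0:(T_ - 1), function(ph) {
    rbind(
      data.frame(phase = ph, chamber = 1, vertex = seq_len(nrow(lvp)),
                 row = lvp[, "row"], col = lvp[, "col"]),
      data.frame(phase = ph, chamber = 2, vertex = seq_len(nrow(lap)),
                 row = lap[, "row"], col = lap[, "col"]))
  }))
  meta <- acquisition_meta(cfg$ps, cfg$frame_interval, cfg$heart_rate, T_)
  list(flow = flow_field(vx, vy), mask = blood_pool_mask(labels),
       contours = contour_set(cont), meta = meta)
}

# separable Gaussian blur with reflecting edges; sigma in pixels
gaussian_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(rad)), 1:n, n - seq_len(rad) + 1)
  conv1 <- function(x) {                       # filter columns of a matrix
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- 0
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Render a cine sequence from a known flow field
#'
#' Frame 0 is a seeded band-limited speckle texture on a bright blood pool
#' over a dark background; each next frame is the previous one advected by
#' the true per-frame displacement using backward (pull) warping with
#' bilinear sampling. Optionally a speed-proportional attenuation
#' `exp(-lambda |v|)` mimics spin dephasing, and Gaussian noise is added.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param truth a [flow_field()] (cm/s) consistent with `cfg`.
#' @param mask a [blood_pool_mask()].
#' @param cfg the [phantom_config()].
#' @return A [cine_sequence()].
#' @export
render_cine <- function(truth, mask, cfg) {
  H <- cfg$grid[1]; W <- cfg$grid[2]; T_ <- cfg$n_phases
  meta <- acquisition_meta(cfg$ps, cfg$frame_interval, cfg$heart_rate, T_)
  disp <- velocity_to_displacement(truth, meta)
  dmax <- max(sqrt(disp$dx^2 + disp$dy^2))
  if (dmax > H / 4)
    stop(sprintf("unrealistic phantom: peak displacement %.1f px exceeds H/4", dmax),
         call. = FALSE)
  set.seed(cfg$seed)
  tex <- gaussian_blur2d(matrix(stats::rnorm(H * W), H, W), cfg$texture_length)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))   # [0, 1]
  pool <- mask$labels[1, , ] > 0L
  frame <- matrix(0.2, H, W)
  frame[pool] <- 0.55 + 0.45 * tex[pool]
  frames <- array(0, c(T_, H, W))
  frames[1, , ] <- frame
  for (t in seq_len(T_ - 1)) {
    frame <- warp_backward(frame, disp$dx[t, , ], disp$dy[t, , ], fill = 0.2)
    if (cfg$attenuation_lambda > 0) {
      sp <- sqrt(truth$vx[t + 1, , ]^2 + truth$vy[t + 1, , ]^2)
      frame <- frame * exp(-cfg$attenuation_lambda * sp)
    }
    frames[t + 1, , ] <- frame
  }
  if (cfg$noise_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), sd = cfg$noise_sd), dim(frames))
  cine_sequence(frames, meta)
}

# backward (pull) bilinear warp: out(p) = img(p - d(p)); constant fill
warp_backward <- function(img, dx, dy, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r <- matrix(0:(H - 1), H, W) - dy
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE) - dx
  r0 <- floor(r); c0 <- floor(c_)
  fr <- r - r0; fc <- c_ - c0
  sample_at <- function(ri, ci) {
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    v <- matrix(fill, H, W)
    v[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  (1 - fr) * (1 - fc) * sample_at(r0, c0) +
    (1 - fr) * fc       * sample_at(r0, c0 + 1) +
    fr       * (1 - fc) * sample_at(r0 + 1, c0) +
    fr       * fc       * sample_at(r0 + 1, c0 + 1)
}

#' Generate a complete phantom
#'
#' Bundles [make_flow_field()] and [render_cine()]; optionally writes the
#' case to disk via [write_case()].
#'
#' @param cfg a [phantom_config()].
#' @param path optional case directory to write.
#' @return An object of class `phantom`: list with `cine`, `truth`, `mask`,
#'   `contours`, `config`.
#' @export
make_phantom <- function(cfg = phantom_config(), path = NULL) {
  ff <- make_flow_field(cfg)
  cine <- render_cine(ff$flow, ff$mask, cfg)
  ph <- structure(list(cine = cine, truth = ff$flow, mask = ff$mask,
                       contours = ff$contours, config = cfg),
                  class = "phantom")
  if (!is.null(path))
    write_case(path, cine, flow = ff$flow, mask = ff$mask, contours = ff$contours)
  ph
}

#' Generate a small phantom cohort for training experiments
#'
#' Emulates inter-subject variability by giving each case its own texture
#' seed and a per-case scale factor, uniform in `1 +/- speed_jitter`,
#' applied jointly to the jet and vortex peak speeds.
#'
#' @param n number of cases.
#' @param seed cohort RNG seed.
#' @param base_cfg configuration shared by all cases (default
#'   [phantom_config_smallmotion()]).
#' @param speed_jitter half-width of the uniform per-case speed scale.
#' @return A named list of `phantom` objects (`case01`, `case02`, ...).
#' @export
make_phantom_cohort <- function(n, seed = 1L, base_cfg = phantom_config_smallmotion(),
                                speed_jitter = 0.15) {
  set.seed(seed)
  scales <- stats::runif(n, 1 - speed_jitter, 1 + speed_jitter)
  seeds <- sample.int(1e6, n)
  out <- lapply(seq_len(n), function(i) {
    cfg <- base_cfg
    cfg$e_peak <- cfg$e_peak * scales[i]
    cfg$a_peak <- cfg$a_peak * scales[i]
    cfg$vortex_peak <- cfg$vortex_peak * scales[i]
    cfg$seed <- seeds[i]
    make_phantom(cfg)
  })
  names(out) <- sprintf("case%02d", seq_len(n))
  out
}
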