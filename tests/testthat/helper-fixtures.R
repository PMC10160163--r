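# Shared fixtures, built in code at test time.

# small default phantom used across test files (cached per session)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(phantom_config_smallmotion(seed = 11L))
    cache
  }
})

# minimal cine sequence with linear-ramp intensities
ramp_cine <- function(T_ = 4, H = 8, W = 8, ps = 1, dt = 0.05, hr = 60) {
  frames <- array(seq_len(T_ * H * W), c(T_, H, W))
  cine_sequence(frames, acquisition_meta(ps, dt, hr, T_))
}

# full-frame single-label mask
full_mask <- function(T_ = 4, H = 8, W = 8, label = 1L) {
  blood_pool_mask(array(label, c(T_, H, W)))
}

# random flow field under a fixed seed
random_flow <- function(T_, H, W, sd = 10, seed = 1) {
  set.seed(seed)
  flow_field(array(rnorm(T_ * H * W, sd = sd), c(T_, H, W)),
             array(rnorm(T_ * H * W, sd = sd), c(T_, H, W)))
}

# independent brute-force point-in-polygon oracle: winding-angle test plus
# explicit distance-to-edge boundary handling (different formulation from the
# crossing-number implementation)
oracle_point_in_polygon <- function(pr, pc, vr, vc, eps = 1e-9) {
  n <- length(vr)
  on_edge <- function(r, c) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      er <- vr[j] - vr[i]; ec <- vc[j] - vc[i]
      L2 <- er^2 + ec^2
      if (L2 == 0) next
      tpar <- ((r - vr[i]) * er + (c - vc[i]) * ec) / L2
      tpar <- min(1, max(0, tpar))
      dr <- r - (vr[i] + tpar * er); dc <- c - (vc[i] + tpar * ec)
      if (dr^2 + dc^2 <= eps^2) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(pr), function(q) {
    r <- pr[q]; c <- pc[q]
    if (on_edge(r, c)) return(TRUE)
    total <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- atan2(vr[i] - r, vc[i] - c)
      a2 <- atan2(vr[j] - r, vc[j] - c)
      da <- a2 - a1
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      total <- total + da
    }
    abs(total) > pi   # winding number != 0
  }, logical(1))
}
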