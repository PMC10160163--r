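test_that("intensity normalization maps the pooled percentiles to 0 and 1", {
  # masked intensities 0..100 -> p5 = 5, p95 = 95 (linear interpolation)
  H <- 101
  frames <- array(0, c(1, H, 2))
  frames[1, , 1] <- 0:100
  frames[1, , 2] <- 999       # outside mask, must not affect percentiles
  labels <- array(0L, c(1, H, 2)); labels[1, , 1] <- 1L
  # n_phases >= 3 is required, so tile three identical phases
  frames3 <- array(0, c(3, H, 2))
  labels3 <- array(0L, c(3, H, 2))
  for (t in 1:3) { frames3[t, , ] <- frames[1, , ]; labels3[t, , ] <- labels[1, , ] }
  seq3 <- cine_sequence(frames3, acquisition_meta(1, 0.04, 60, 3))
  res <- normalize_intensities(seq3, blood_pool_mask(labels3))
  expect_equal(res$stats$p5, 5)
  expect_equal(res$stats$p95, 95)
  # sort-based percentile oracle with linear interpolation
  pooled <- sort(frames3[labels3 > 0])
  oracle_q <- function(p) {
    h <- (length(pooled) - 1) * p
    lo <- floor(h)
    pooled[lo + 1] * (1 - (h - lo)) + pooled[min(lo + 2, length(pooled))] * (h - lo)
  }
  expect_equal(res$stats$p5, oracle_q(0.05))
  expect_equal(res$stats$p95, oracle_q(0.95))
  mid <- which(frames3[1, , 1] == 50)
  expect_equal(res$cine$frames[1, mid, 1], (50 - 5) / 90)
  # values map exactly: P5 -> 0, P95 -> 1; tails are NOT clipped
  expect_equal(res$cine$frames[1, 6, 1], 0)
  expect_equal(res$cine$frames[1, 96, 1], 1)
  expect_gt(res$cine$frames[1, 1, 2], 1)     # unmasked bright pixel stays > 1
  expect_lt(res$cine$frames[1, 1, 1], 0)     # intensity 0 < p5 maps below 0
})

test_that("normalization is invariant under positive affine intensity transforms", {
  ph <- tiny_phantom()
  base <- normalize_intensities(ph$cine, ph$mask)$cine$frames
  for (ab in list(c(3.2, 10), c(0.5, -4))) {
    scaled <- cine_sequence(ab[1] * ph$cine$frames + ab[2], ph$cine$meta)
    res <- normalize_intensities(scaled, ph$mask)$cine$frames
    expect_equal(res, base, tolerance = 1e-12)
  }
})

test_that("normalization rejects empty or constant masked input", {
  frames <- array(7, c(3, 8, 8))
  meta <- acquisition_meta(1, 0.04, 60, 3)
  seq_ <- cine_sequence(frames, meta)
  expect_error(normalize_intensities(seq_, blood_pool_mask(array(0L, c(3, 8, 8)))),
               "empty")
  expect_error(normalize_intensities(seq_, full_mask(3)), "degenerate")
})

test_that("velocity/displacement conversion follows dt * v / ps with unit handling", {
  meta <- acquisition_meta(1.25, 0.04, 60, 3)
  v <- flow_field(array(2.5, c(3, 4, 4)), array(-2.5, c(3, 4, 4)))
  d <- velocity_to_displacement(v, meta)
  # 2.5 cm/s = 25 mm/s; 25 * 0.04 / 1.25 = 0.8 px
  expect_equal(d$dx[1, 1, 1], 0.8)
  expect_equal(d$dy[1, 1, 1], -0.8)
  zero <- velocity_to_displacement(flow_field(array(0, c(3, 4, 4)),
                                              array(0, c(3, 4, 4))), meta)
  expect_true(all(zero$dx == 0) && all(zero$dy == 0))
  neg <- velocity_to_displacement(flow_field(-v$vx, -v$vy), meta)
  expect_equal(neg$dx, -d$dx)
  meta2 <- acquisition_meta(1, 0.05, 60, 3)
  v2 <- displacement_to_velocity(displacement_field(array(1, c(3, 2, 2)),
                                                    array(0, c(3, 2, 2))), meta2)
  expect_equal(v2$vx[1, 1, 1], 2)   # 1 px * 1 mm / 0.05 s = 20 mm/s = 2 cm/s
})

test_that("velocity -> displacement -> velocity round-trips to floating precision", {
  meta <- acquisition_meta(c(0.95, 1.25), 0.0417, 72, 5)
  v <- random_flow(5, 6, 6, sd = 30, seed = 4)
  back <- displacement_to_velocity(velocity_to_displacement(v, meta), meta)
  expect_equal(back$vx, v$vx, tolerance = 1e-10)
  expect_equal(back$vy, v$vy, tolerance = 1e-10)
})

test_that("heart-rate exclusion is strict at more than six bpm", {
  expect_equal(check_heart_rate(70, 77), "exclude")
  expect_equal(check_heart_rate(70, 76), "keep")
  expect_equal(check_heart_rate(70, 70), "keep")
  expect_equal(check_heart_rate(77, 70), "exclude")
  tab <- heart_rate_report(data.frame(case_id = c("a", "b"),
                                      hr_cine = c(60, 60), hr_flow = c(67, 65)))
  expect_equal(tab$decision, c("exclude", "keep"))
  f <- withr::local_tempfile(fileext = ".csv")
  heart_rate_report(data.frame(case_id = "a", hr_cine = 60, hr_flow = 61), file = f)
  expect_true(file.exists(f))
})

test_that("trilinear projection reproduces grid slices and node midpoints", {
  set.seed(2)
  vol <- array(rnorm(5 * 5 * 4 * 3), c(5, 5, 4, 3))
  # plane coincident with grid slice z-index 2 (0-based 1), axes = grid axes
  pl <- plane_geometry(origin = c(0, 0, 1), e_x = c(1, 0, 0), e_y = c(0, 1, 0),
                       spacing = c(1, 1), extent = c(5, 5))
  res <- project_volume_velocity(vol, grid_origin = c(0, 0, 0),
                                 grid_spacing = c(1, 1, 1), plane = pl)
  expect_equal(res$n_out_of_bounds, 0)
  for (r in 1:5) for (c in 1:5) {
    expect_equal(res$vx[r, c], vol[c, r, 2, 1])
    expect_equal(res$vy[r, c], vol[c, r, 2, 2])
  }
  # query at the midpoint between two nodes along x
  pl2 <- plane_geometry(origin = c(0.5, 2, 1), e_x = c(1, 0, 0), e_y = c(0, 1, 0),
                        spacing = c(1, 1), extent = c(1, 1))
  res2 <- project_volume_velocity(vol, c(0, 0, 0), c(1, 1, 1), pl2)
  expect_equal(res2$vx[1, 1], mean(vol[1:2, 3, 2, 1]))
})

test_that("projection discards through-plane flow and flags out-of-bounds pixels", {
  vol <- array(0, c(4, 4, 4, 3))
  vol[, , , 3] <- 11   # purely through-plane for an xy plane
  pl <- plane_geometry(c(0, 0, 1.5), c(1, 0, 0), c(0, 1, 0), c(1, 1), c(4, 4))
  res <- project_volume_velocity(vol, c(0, 0, 0), c(1, 1, 1), pl)
  expect_true(all(res$vx == 0) && all(res$vy == 0))
  pl_oob <- plane_geometry(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(2, 2), c(4, 4))
  res2 <- project_volume_velocity(vol, c(0, 0, 0), c(1, 1, 1), pl_oob)
  expect_gt(res2$n_out_of_bounds, 0)
})

test_that("trilinear interpolation is exact for trilinear fields", {
  # v(x,y,z) = a + bx + cy + dz + exy + fxz + gyz + hxyz per component
  co <- matrix(rnorm(24), 8, 3)
  f <- function(x, y, z, k)
    co[1,k] + co[2,k]*x + co[3,k]*y + co[4,k]*z + co[5,k]*x*y +
    co[6,k]*x*z + co[7,k]*y*z + co[8,k]*x*y*z
  vol <- array(0, c(4, 4, 4, 3))
  for (i in 1:4) for (j in 1:4) for (l in 1:4) for (k in 1:3)
    vol[i, j, l, k] <- f(i - 1, j - 1, l - 1, k)
  pl <- plane_geometry(c(0.3, 0.7, 1.2), c(1, 0, 0), c(0, 1, 0), c(0.45, 0.4), c(4, 4))
  res <- project_volume_velocity(vol, c(0, 0, 0), c(1, 1, 1), pl)
  for (r in 1:4) for (c in 1:4) {
    x <- 0.3 + (c - 1) * 0.45; y <- 0.7 + (r - 1) * 0.4; z <- 1.2
    expect_equal(res$vx[r, c], f(x, y, z, 1), tolerance = 1e-10)
    expect_equal(res$vy[r, c], f(x, y, z, 2), tolerance = 1e-10)
  }
})
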