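mk_flow <- function(vx, vy) flow_field(vx, vy)

one_pixel_setup <- function(pvx, pvy, gvx, gvy) {
  T_ <- 3; H <- 4; W <- 4
  vx <- array(0, c(T_, H, W)); vy <- array(0, c(T_, H, W))
  gx <- array(0, c(T_, H, W)); gy <- array(0, c(T_, H, W))
  vx[1, 2, 2] <- pvx; vy[1, 2, 2] <- pvy
  gx[1, 2, 2] <- gvx; gy[1, 2, 2] <- gvy
  labels <- array(0L, c(T_, H, W)); labels[1, 2, 2] <- 1L
  list(pred = mk_flow(vx, vy), ref = mk_flow(gx, gy),
       mask = blood_pool_mask(labels))
}

test_that("velocity EPE gates on reference speed and matches hand values", {
  s <- one_pixel_setup(10, 0, 6, 8)
  expect_equal(velocity_epe(s$pred, s$ref, s$mask, vmin = 5), sqrt(80))
  expect_equal(velocity_epe(s$ref, s$ref, s$mask, vmin = 5), 0)
  expect_error(velocity_epe(s$pred, s$ref, s$mask, vmin = Inf), "qualify")
  # reference speed 10 > 5 qualifies even though prediction is slow
  s2 <- one_pixel_setup(0.1, 0, 10, 0)
  expect_equal(velocity_epe(s2$pred, s2$ref, s2$mask), 9.9)
  # gate conditions on the reference, not the prediction
  s3 <- one_pixel_setup(100, 0, 1, 0)
  expect_error(velocity_epe(s3$pred, s3$ref, s3$mask, vmin = 5), "qualify")
})

test_that("angle error reproduces parallel, opposite and orthogonal cases", {
  s <- one_pixel_setup(2, 0, 14, 0)
  expect_equal(as.numeric(angle_error(s$pred, s$ref, s$mask)), 0)
  s2 <- one_pixel_setup(-3, 0, 14, 0)
  expect_equal(as.numeric(angle_error(s2$pred, s2$ref, s2$mask)), 180)
  s3 <- one_pixel_setup(1, 0, 0, 7)
  expect_equal(as.numeric(angle_error(s3$pred, s3$ref, s3$mask)), 90)
  # zero-magnitude predictions among qualifying pixels are excluded and counted
  s4 <- one_pixel_setup(0, 0, 14, 0)
  expect_error(angle_error(s4$pred, s4$ref, s4$mask), "zero magnitude")
})

test_that("angle error matches a brute-force oracle and stays in [0, 180]", {
  set.seed(17)
  for (rep in 1:20) {
    T_ <- 1; H <- 8; W <- 8
    pred <- mk_flow(array(rnorm(H * W, sd = 8), c(T_, H, W)),
                    array(rnorm(H * W, sd = 8), c(T_, H, W)))
    ref <- mk_flow(array(rnorm(H * W, sd = 8), c(T_, H, W)),
                   array(rnorm(H * W, sd = 8), c(T_, H, W)))
    labels <- array(as.integer(matrix(runif(H * W) > 0.3, H, W)), c(T_, H, W))
    mask <- blood_pool_mask(labels)
    vmin <- 2
    angles <- c(); epes <- c()
    for (i in 1:H) for (j in 1:W) {
      if (labels[1, i, j] == 0L) next
      g <- c(ref$vx[1, i, j], ref$vy[1, i, j])
      p <- c(pred$vx[1, i, j], pred$vy[1, i, j])
      if (sqrt(sum(g^2)) <= vmin) next
      epes <- c(epes, sqrt(sum((p - g)^2)))
      if (sum(p^2) == 0 || sum(g^2) == 0) next
      cosv <- sum(p * g) / sqrt(sum(p^2) * sum(g^2))
      angles <- c(angles, acos(max(-1, min(1, cosv))) * 180 / pi)
    }
    if (length(epes) == 0) next
    expect_equal(velocity_epe(pred, ref, mask, vmin), mean(epes), tolerance = 1e-9)
    a <- as.numeric(angle_error(pred, ref, mask, vmin))
    expect_equal(a, mean(angles), tolerance = 1e-9)
    expect_gte(a, 0); expect_lte(a, 180)
    # invariant to positive rescaling of either field
    pred2 <- mk_flow(3.7 * pred$vx, 3.7 * pred$vy)
    expect_equal(as.numeric(angle_error(pred2, ref, mask, vmin)), a,
                 tolerance = 1e-9)
  }
})

test_that("relative error is the signed ratio of mean speeds", {
  ph <- tiny_phantom()
  half <- mk_flow(0.5 * ph$truth$vx, 0.5 * ph$truth$vy)
  expect_equal(relative_error(half, ph$truth, ph$mask), -50)
  expect_equal(relative_error(ph$truth, ph$truth, ph$mask), 0)
  # speeds {1,3} vs {2,2}: means equal -> 0 %
  T_ <- 3; H <- 2; W <- 2
  vx <- array(0, c(T_, H, W)); vx[1, 1, 1] <- 1; vx[1, 1, 2] <- 3
  gx <- array(0, c(T_, H, W)); gx[1, 1, 1] <- 2; gx[1, 1, 2] <- 2
  labels <- array(0L, c(T_, H, W)); labels[1, 1, ] <- 1L
  mask <- blood_pool_mask(labels)
  zeros <- array(0, c(T_, H, W))
  expect_equal(relative_error(mk_flow(vx, zeros), mk_flow(gx, zeros), mask), 0)
})

test_that("velocity PCC correlates the phase-averaged speed series", {
  ph <- tiny_phantom()
  expect_equal(velocity_pcc(ph$truth, ph$truth, ph$mask), 1.0)
  doubled <- mk_flow(2 * ph$truth$vx, 2 * ph$truth$vy)
  expect_equal(velocity_pcc(doubled, ph$truth, ph$mask), 1.0)
  flat <- mk_flow(array(1, dim(ph$truth$vx)), array(0, dim(ph$truth$vx)))
  expect_warning(r <- velocity_pcc(flat, ph$truth, ph$mask), "zero-variance")
  expect_true(is.na(r))
  # hand case: series (1,2,3) vs (2,4,6) -> r = 1
  T_ <- 3; H <- 2; W <- 2
  vx <- array(rep(1:3, each = 0), c(T_, H, W))
  for (t in 1:3) vx[t, , ] <- t
  gx <- 2 * vx
  mask <- full_mask(T_, H, W)
  zeros <- array(0, c(T_, H, W))
  expect_equal(velocity_pcc(mk_flow(vx, zeros), mk_flow(gx, zeros), mask), 1.0)
})

test_that("velocity histograms normalize and accumulate out-of-range mass", {
  T_ <- 3; H <- 2; W <- 2
  vx <- array(10, c(T_, H, W))
  mask <- full_mask(T_, H, W)
  h <- velocity_histogram(mk_flow(vx, 0 * vx), mask, edges = c(0, 20))
  expect_equal(h$mass, 1)
  # two equal-count speed groups into two bins
  vx2 <- array(c(rep(1, 6), rep(3, 6)), c(T_, H, W))
  h2 <- velocity_histogram(mk_flow(vx2, 0 * vx2), mask, edges = c(0, 2, 4))
  expect_equal(h2$mass, c(0.5, 0.5))
  # out-of-range speeds land in the end bins; mass still sums to 1
  ph <- tiny_phantom()
  h3 <- velocity_histogram(ph$truth, ph$mask, edges = seq(0, 4, by = 1))
  expect_equal(sum(h3$mass), 1)
  expect_gt(h3$mass[4], 0)   # speeds above 4 cm/s pushed into last bin
  expect_error(velocity_histogram(ph$truth, ph$mask, edges = c(3, 1)),
               "increasing")
})

test_that("threshold sweep is consistent with single-threshold metrics", {
  ph <- tiny_phantom()
  noisy <- mk_flow(ph$truth$vx + 0.5, ph$truth$vy - 0.3)
  tab <- threshold_sweep(noisy, ph$truth, ph$mask, vmins = c(0, 2, 5, 8))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$epe[3], velocity_epe(noisy, ph$truth, ph$mask, 5))
  expect_equal(tab$angle_error[3],
               as.numeric(angle_error(noisy, ph$truth, ph$mask, 5)))
  expect_true(all(diff(tab$n_pixels) <= 0))
  self <- threshold_sweep(ph$truth, ph$truth, ph$mask, vmins = c(0, 5))
  expect_true(all(self$epe == 0))
  huge <- threshold_sweep(noisy, ph$truth, ph$mask, vmins = 1e6)
  expect_true(is.na(huge$epe[1]))
  expect_equal(huge$n_pixels[1], 0L)
})

test_that("per-chamber metrics partition the aggregate pixel count", {
  ph <- tiny_phantom()
  noisy <- mk_flow(ph$truth$vx * 0.8, ph$truth$vy * 0.8)
  tab <- evaluate_regions(noisy, ph$truth, ph$mask, vmin = 2)
  expect_setequal(tab$region, c("4CH", "LV", "LA"))
  agg <- tab$n_pixels[tab$region == "4CH"]
  expect_equal(sum(tab$n_pixels[tab$region != "4CH"]), agg)
  expect_equal(tab$relative_error[tab$region == "4CH"], -20, tolerance = 1e-9)
  coh <- evaluate_cohort(list(tab, tab))
  expect_equal(coh$mean[coh$region == "4CH" & coh$metric == "relative_error"], -20)
  expect_equal(coh$sd[coh$region == "4CH" & coh$metric == "relative_error"], 0)
})

test_that("gated accuracy counts pixels with EPE under the speed percentile", {
  ph <- tiny_phantom()
  expect_equal(gated_accuracy(ph$truth, ph$truth, ph$mask, vmin = 2), 1)
  # a grossly wrong prediction leaves few pixels under the bound
  wild <- flow_field(ph$truth$vx + 100, ph$truth$vy)
  expect_equal(gated_accuracy(wild, ph$truth, ph$mask, vmin = 2), 0)
  expect_error(gated_accuracy(ph$truth, ph$truth, ph$mask, vmin = Inf), "qualify")
})

test_that("velocity and displacement EPE are unit-consistent", {
  # with isotropic spacing, EPE(velocity) = EPE(displacement) * ps / (10 dt)
  ph <- tiny_phantom()
  meta <- ph$cine$meta
  noisy <- mk_flow(ph$truth$vx + 1, ph$truth$vy - 2)
  dp <- velocity_to_displacement(noisy, meta)
  dg <- velocity_to_displacement(ph$truth, meta)
  t <- 19
  m <- ph$mask$labels[t, , ] > 0
  epe_disp <- epe_loss(list(dx = dp$dx[t, , ], dy = dp$dy[t, , ]),
                       list(dx = dg$dx[t, , ], dy = dg$dy[t, , ]), m)
  epe_vel_direct <- mean(sqrt((noisy$vx[t, , ][m] - ph$truth$vx[t, , ][m])^2 +
                              (noisy$vy[t, , ][m] - ph$truth$vy[t, , ][m])^2))
  expect_equal(epe_disp * meta$pixel_spacing[1] / (10 * meta$frame_interval),
               epe_vel_direct, tolerance = 1e-10)
})
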