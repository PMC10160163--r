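test_that("network outputs four full-resolution 2-channel predictions", {
  cfg <- network_config(window = 9, base_channels = 4, seed = 3)
  net <- build_network(cfg)
  x <- array(rnorm(64 * 64 * 9), c(64, 64, 9))
  out <- flownet_forward(net, x, train = FALSE)
  expect_length(out$preds, 4)
  for (p in out$preds) {
    expect_equal(dim(p), c(64L, 64L, 2L, 1L))
    expect_true(all(is.finite(p)))
  }
  expect_error(flownet_forward(net, array(0, c(60, 64, 9))), "divisible by 16")
  expect_error(flownet_forward(net, array(0, c(64, 64, 5))), "window")
})

test_that("initialization is deterministic under the seed and size-independent", {
  cfg <- network_config(window = 5, base_channels = 4, seed = 21)
  n1 <- build_network(cfg); n2 <- build_network(cfg)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(network_config(window = 5, base_channels = 4, seed = 22))
  expect_false(identical(n1$params, n3$params))
  # fully convolutional: parameter count does not depend on input size
  x16 <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  x32 <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  expect_silent(flownet_forward(n1, x16, train = FALSE))
  expect_silent(flownet_forward(n1, x32, train = FALSE))
  expect_equal(n_parameters(n1), n_parameters(n2))
})

test_that("epe_loss matches its definition on hand-computed cases", {
  H <- 4; W <- 4
  mk <- function(dx, dy) array(c(dx, dy), c(H, W, 2))
  zero <- mk(matrix(0, H, W), matrix(0, H, W))
  mask1 <- matrix(0, H, W); mask1[2, 2] <- 1
  pred <- mk(matrix(1, H, W), matrix(1, H, W))
  expect_equal(epe_loss(pred, pred, matrix(1, H, W)), 0)
  expect_equal(epe_loss(pred, zero, mask1), sqrt(2))
  mask2 <- mask1; mask2[3, 3] <- 1
  pred2 <- zero; pred2[2, 2, 1] <- 3; pred2[2, 2, 2] <- 4
  expect_equal(epe_loss(pred2, zero, mask2), (5 + 0) / 2)
  expect_error(epe_loss(pred, zero, matrix(0, H, W)), "empty mask")
})

test_that("epe_loss agrees with a brute-force double loop on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    H <- 8; W <- 8
    pred <- array(rnorm(H * W * 2), c(H, W, 2))
    gt <- array(rnorm(H * W * 2), c(H, W, 2))
    mask <- matrix(runif(H * W) > 0.4, H, W)
    if (!any(mask)) mask[1, 1] <- TRUE
    acc <- 0; M <- 0
    for (i in 1:H) for (j in 1:W) if (mask[i, j]) {
      acc <- acc + sqrt((pred[i, j, 1] - gt[i, j, 1])^2 +
                        (pred[i, j, 2] - gt[i, j, 2])^2)
      M <- M + 1
    }
    expect_equal(epe_loss(pred, gt, mask), acc / M, tolerance = 1e-9)
    # symmetry and mean (not sum) behaviour
    expect_equal(epe_loss(pred, gt, mask), epe_loss(gt, pred, mask))
  }
})

test_that("epe_loss is a per-pixel metric: mean form and triangle inequality", {
  set.seed(5)
  H <- 6; W <- 6
  a <- array(rnorm(H * W * 2), c(H, W, 2))
  b <- array(rnorm(H * W * 2), c(H, W, 2))
  c_ <- array(rnorm(H * W * 2), c(H, W, 2))
  mask <- matrix(TRUE, H, W)
  expect_lte(epe_loss(a, c_, mask), epe_loss(a, b, mask) + epe_loss(b, c_, mask) + 1e-12)
  # duplicating pixels with identical errors leaves the mean unchanged
  a2 <- array(0, c(H, 2 * W, 2)); g2 <- array(0, c(H, 2 * W, 2))
  a2[, 1:W, ] <- a; a2[, W + 1:W, ] <- a
  g2[, 1:W, ] <- b; g2[, W + 1:W, ] <- b
  expect_equal(epe_loss(a2, g2, matrix(TRUE, H, 2 * W)), epe_loss(a, b, mask))
})

test_that("total loss combines the four heads with the auxiliary weights", {
  set.seed(8)
  H <- 8; W <- 8
  gt <- array(rnorm(H * W * 2), c(H, W, 2))
  p <- array(rnorm(H * W * 2), c(H, W, 2))
  mask <- matrix(runif(H * W) > 0.3, H, W)
  preds <- list(p, p, p, p)
  e <- epe_loss(p, gt, mask)
  expect_equal(total_loss(preds, gt, mask, c(0, 0, 0)), e)
  expect_equal(total_loss(preds, gt, mask, c(1, 1, 1)), 4 * e)
  expect_equal(total_loss(list(gt, gt, gt, gt), gt, mask, c(0.25, 0.5, 0.75)), 0)
  expect_equal(total_loss(preds, gt, mask, c(0.25, 0.5, 0.75)), 2.5 * e)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  # random head init so gradients reach the trunk in a single backward pass
  cfg <- network_config(window = 3, base_channels = 2, head_init = "random",
                        seed = 7)
  net <- build_network(cfg)
  H <- 16; W <- 16; N <- 2
  x <- array(rnorm(H * W * 3 * N), c(H, W, 3, N))
  gt <- array(rnorm(H * W * 2 * N, sd = 0.5), c(H, W, 2, N))
  mask <- array(runif(H * W * N) > 0.3, c(H, W, N))
  lossfun <- function()
    total_loss(flownet_forward(net, x, TRUE)$preds, gt, mask, cfg$aux_weights)
  fw <- flownet_forward(net, x, train = TRUE)
  dp <- total_loss_grads(fw$preds, gt, array(as.numeric(mask), dim(mask)),
                         cfg$aux_weights)
  grads <- flownet_backward(net, fw$tape, dp)
  eps <- 1e-5
  for (nm in sample(names(net$params), 8)) {
    i <- sample(length(net$params[[nm]]), 1)
    orig <- net$params[[nm]][i]
    net$params[[nm]][i] <- orig + eps; lp <- lossfun()
    net$params[[nm]][i] <- orig - eps; lm <- lossfun()
    net$params[[nm]][i] <- orig
    num <- (lp - lm) / (2 * eps)
    rel <- abs(num - grads[[nm]][i]) / max(1e-3, abs(num) + abs(grads[[nm]][i]))
    expect_lt(rel, 5e-3, label = paste("gradient mismatch for", nm))
  }
})

test_that("checkpoints round-trip parameters and predictions", {
  cfg <- network_config(window = 3, base_channels = 2, seed = 5)
  net <- build_network(cfg)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  dir <- withr::local_tempdir()
  save_network(net, dir)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  net2 <- load_network(dir)
  expect_identical(net2$params, net$params)
  expect_equal(flownet_predict(net2, x), flownet_predict(net, x))
  expect_error(load_network(file.path(dir, "missing")), "checkpoint")
})

test_that("deep supervision wires a gradient into every parameter tensor", {
  set.seed(9)
  cfg <- network_config(window = 3, base_channels = 2, seed = 13)
  net <- build_network(cfg)
  # batch of 2 so batch-norm statistics are non-degenerate at the coarsest
  # (1x1) scale
  H <- 16; W <- 16; N <- 2
  x <- array(rnorm(H * W * 3 * N), c(H, W, 3, N))
  gt <- array(rnorm(H * W * 2 * N), c(H, W, 2, N))
  mask <- array(1, c(H, W, N))
  # with zero-initialized heads the trunk only sees gradients once the heads
  # have moved, so take one optimizer step before checking the wiring
  step <- function() {
    fw <- flownet_forward(net, x, train = TRUE)
    dp <- total_loss_grads(fw$preds, gt, mask, c(0.25, 0.5, 0.75))
    flownet_backward(net, fw$tape, dp)
  }
  g1 <- step()
  for (nm in names(net$params)) net$params[[nm]] <- net$params[[nm]] - 1e-2 * g1[[nm]]
  grads <- step()
  expect_setequal(names(grads), names(net$params))
  for (nm in names(net$params))
    expect_true(any(grads[[nm]] != 0), label = paste("nonzero gradient for", nm))
})
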