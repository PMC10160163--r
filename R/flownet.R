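#' Network configuration
#'
#' Hyperparameters of the displacement-regression network: a residual U-Net
#' variant with a four-stage contracting path (one 2x2 max-pooling followed
#' by three stride-2 1x1 convolutions), concatenation skip connections, and
#' three deeply-supervised auxiliary 2-channel displacement heads inserted
#' before each decoder up-sampling (scales 1/8, 1/4, 1/2), each resampled to
#' full resolution by nearest-neighbour interpolation. Prediction 4 — the
#' full-resolution head — is the final output.
#'
#' @param window number of input frames (odd, >= 3); the central frame is the
#'   target phase, flanked symmetrically by its temporal neighbours. The
#'   default 9 corresponds to the target image plus 8 neighbouring phases.
#' @param base_channels channels at the finest scale, doubling per level.
#' @param aux_weights loss weights `(w1, w2, w3)` of the three auxiliary
#'   heads, ordered coarse (1/8) to fine (1/2).
#' @param head_init `"zero"` (default) initializes the four prediction
#'   heads to zero so training starts from the zero-flow prior — the
#'   displacement-regression analogue of starting residual branches at
#'   identity, which removes the early epochs otherwise spent shrinking
#'   random head output; `"random"` uses He initialization everywhere.
#' @param seed weight-initialization seed.
#' @return An object of class `network_config`.
#' @export
network_config <- function(window = 9L, base_channels = 32L,
                           aux_weights = c(0.25, 0.5, 0.75),
                           head_init = c("zero", "random"), seed = 1L) {
  window <- as.integer(window)
  head_init <- match.arg(head_init)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (length(aux_weights) != 3L || any(aux_weights < 0))
    stop("aux_weights must be three nonnegative numbers", call. = FALSE)
  structure(list(window = window, base_channels = as.integer(base_channels),
                 levels = 4L, aux_weights = as.numeric(aux_weights),
                 head_init = head_init, seed = as.integer(seed)),
            class = "network_config")
}

he_init <- function(fan_in, cout) {
  matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
}

new_conv <- function(params, name, k, cin, cout, bias = TRUE) {
  params[[paste0(name, ".W")]] <- he_init(k * k * cin, cout)
  # convolutions followed by batch norm carry no bias (it would be absorbed
  # by the normalization and receive a zero gradient)
  if (bias) params[[paste0(name, ".b")]] <- numeric(cout)
  params
}
new_bn <- function(params, bn, name, c_) {
  params[[paste0(name, ".gamma")]] <- rep(1, c_)
  params[[paste0(name, ".beta")]] <- numeric(c_)
  bn[[paste0(name, ".rm")]] <- numeric(c_)
  bn[[paste0(name, ".rv")]] <- rep(1, c_)
  list(params = params, bn = bn)
}
new_cbr <- function(st, name, k, cin, cout) {
  st$params <- new_conv(st$params, paste0(name, ".conv"), k, cin, cout, bias = FALSE)
  r <- new_bn(st$params, st$bn, paste0(name, ".bn"), cout)
  st$params <- r$params; st$bn <- r$bn
  st
}
new_res <- function(st, name, cin, cout) {
  st <- new_cbr(st, paste0(name, ".c1"), 3L, cin, cout)
  st <- new_cbr(st, paste0(name, ".c2"), 3L, cout, cout)
  if (cin != cout) st <- new_cbr(st, paste0(name, ".proj"), 1L, cin, cout)
  st
}

#' Build the displacement-regression network
#'
#' Instantiates all parameters (He initialization, deterministic under
#' `cfg$seed`) and returns a model handle. The network is fully
#' convolutional, so the parameter count is independent of the input size;
#' inputs must have height and width divisible by 16 (four downsamplings) —
#' other sizes are rejected so the caller can decide how to pad.
#'
#' @param cfg a [network_config()].
#' @return An environment of class `flownet` with elements `params` (named
#'   list of weight matrices/vectors), `bn` (running statistics), `cfg`.
#' @export
build_network <- function(cfg = network_config()) {
  set.seed(cfg$seed)
  b <- cfg$base_channels
  st <- list(params = list(), bn = list())
  st <- new_cbr(st, "stem", 3L, cfg$window, b)
  st <- new_res(st, "enc0", b, b)
  st <- new_res(st, "enc1", b, 2L * b)
  st <- new_cbr(st, "down2", 1L, 2L * b, 4L * b)
  st <- new_res(st, "enc2", 4L * b, 4L * b)
  st <- new_cbr(st, "down3", 1L, 4L * b, 8L * b)
  st <- new_res(st, "enc3", 8L * b, 8L * b)
  st <- new_cbr(st, "down4", 1L, 8L * b, 16L * b)
  st <- new_res(st, "bott", 16L * b, 16L * b)
  st <- new_res(st, "dec3", 24L * b, 8L * b)
  st$params <- new_conv(st$params, "aux1", 1L, 8L * b, 2L)
  st <- new_res(st, "dec2", 12L * b, 4L * b)
  st$params <- new_conv(st$params, "aux2", 1L, 4L * b, 2L)
  st <- new_res(st, "dec1", 6L * b, 2L * b)
  st$params <- new_conv(st$params, "aux3", 1L, 2L * b, 2L)
  st <- new_res(st, "dec0", 3L * b, b)
  st$params <- new_conv(st$params, "head", 1L, b, 2L)
  if (cfg$head_init == "zero")
    for (nm in c("aux1.W", "aux2.W", "aux3.W", "head.W"))
      st$params[[nm]][] <- 0
  net <- new.env(parent = emptyenv())
  net$params <- st$params
  net$bn <- st$bn
  net$cfg <- cfg
  class(net) <- "flownet"
  net
}

#' Number of trainable parameters
#' @param net a `flownet`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, integer(1)))

#' Save a network checkpoint
#'
#' Writes the parameters and batch-norm running statistics in R's native
#' serialized form (`checkpoint.rds`) next to a human-readable
#' `architecture.json` manifest (configuration, parameter count, package
#' version) for reproducibility.
#'
#' @param net a `flownet`.
#' @param path checkpoint directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = net$params, bn = net$bn, cfg = net$cfg),
          file.path(path, "checkpoint.rds"))
  jsonlite::write_json(
    list(config = unclass(net$cfg), n_parameters = n_parameters(net),
         package = "cineflowr",
         version = as.character(utils::packageVersion("cineflowr"))),
    file.path(path, "architecture.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path directory written by [save_network()].
#' @return A `flownet` ready for [flownet_predict()] or further training.
#' @export
load_network <- function(path) {
  f <- file.path(path, "checkpoint.rds")
  if (!file.exists(f)) stop("no checkpoint.rds under ", path, call. = FALSE)
  st <- readRDS(f)
  net <- new.env(parent = emptyenv())
  net$params <- st$params
  net$bn <- st$bn
  net$cfg <- st$cfg
  class(net) <- "flownet"
  net
}

# --- forward -----------------------------------------------------------------

cbr_f <- function(net, tape, name, x, k, stride = 1L, relu = TRUE, train = TRUE) {
  p <- net$params
  cv <- conv_fwd(p[[paste0(name, ".conv.W")]], NULL, x, k, stride)
  bnm <- paste0(name, ".bn")
  bn <- bn_fwd(p[[paste0(bnm, ".gamma")]], p[[paste0(bnm, ".beta")]], cv$y, train,
               net$bn[[paste0(bnm, ".rm")]], net$bn[[paste0(bnm, ".rv")]])
  if (train) {
    net$bn[[paste0(bnm, ".rm")]] <- bn$rm
    net$bn[[paste0(bnm, ".rv")]] <- bn$rv
  }
  y <- bn$y
  rl <- NULL
  if (relu) { r <- relu_fwd(y); y <- r$y; rl <- r$cache }
  tape[[name]] <- list(conv = cv$cache, bn = bn$cache, relu = rl)
  list(y = y, tape = tape)
}

cbr_b <- function(net, tape, grads, name, dy) {
  tc <- tape[[name]]
  if (!is.null(tc$relu)) dy <- relu_bwd(tc$relu, dy)
  bb <- bn_bwd(tc$bn, dy)
  bnm <- paste0(name, ".bn")
  grads[[paste0(bnm, ".gamma")]] <- grads_add(grads[[paste0(bnm, ".gamma")]], bb$dgamma)
  grads[[paste0(bnm, ".beta")]] <- grads_add(grads[[paste0(bnm, ".beta")]], bb$dbeta)
  cb <- conv_bwd(tc$conv, bb$dx)
  grads[[paste0(name, ".conv.W")]] <- grads_add(grads[[paste0(name, ".conv.W")]], cb$dW)
  list(dx = cb$dx, grads = grads)
}

res_f <- function(net, tape, name, x, cin, cout, train = TRUE) {
  r1 <- cbr_f(net, tape, paste0(name, ".c1"), x, 3L, relu = TRUE, train = train)
  r2 <- cbr_f(net, r1$tape, paste0(name, ".c2"), r1$y, 3L, relu = FALSE, train = train)
  tape <- r2$tape
  if (cin != cout) {
    pr <- cbr_f(net, tape, paste0(name, ".proj"), x, 1L, relu = FALSE, train = train)
    tape <- pr$tape
    sc <- pr$y
  } else sc <- x
  s <- r2$y + sc
  rl <- relu_fwd(s)
  tape[[paste0(name, ".out")]] <- list(relu = rl$cache, proj = cin != cout)
  list(y = rl$y, tape = tape)
}

res_b <- function(net, tape, grads, name, dy) {
  oc <- tape[[paste0(name, ".out")]]
  ds <- relu_bwd(oc$relu, dy)
  b2 <- cbr_b(net, tape, grads, paste0(name, ".c2"), ds)
  b1 <- cbr_b(net, tape, b2$grads, paste0(name, ".c1"), b2$dx)
  grads <- b1$grads
  dx <- b1$dx
  if (oc$proj) {
    bp <- cbr_b(net, tape, grads, paste0(name, ".proj"), ds)
    grads <- bp$grads
    dx <- dx + bp$dx
  } else dx <- dx + ds
  list(dx = dx, grads = grads)
}

grads_add <- function(cur, g) if (is.null(cur)) g else cur + g

#' Network forward pass
#'
#' @param net a `flownet` from [build_network()].
#' @param x input array `[H, W, window, N]` (window frames as channels) or
#'   `[H, W, window]` for a single sample.
#' @param train logical; `TRUE` uses batch statistics (and updates running
#'   ones), `FALSE` uses running statistics.
#' @return A list with `preds` — four arrays `[H, W, 2, N]` (auxiliary heads
#'   1..3 coarse-to-fine, then the final full-resolution prediction 4) — and
#'   `tape` (caches for [flownet_backward()]).
#' @export
flownet_forward <- function(net, x, train = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input height and width must be divisible by 16", call. = FALSE)
  if (d[3] != net$cfg$window)
    stop("input channel count must equal the configured window", call. = FALSE)
  x <- aperm(x, c(1, 2, 4, 3))        # to internal channel-last layout
  b <- net$cfg$base_channels
  tape <- list()
  r <- cbr_f(net, tape, "stem", x, 3L, train = train); tape <- r$tape
  r <- res_f(net, tape, "enc0", r$y, b, b, train); tape <- r$tape; s0 <- r$y
  mp <- maxpool_fwd(s0); tape$pool <- mp$cache
  r <- res_f(net, tape, "enc1", mp$y, b, 2L * b, train); tape <- r$tape; s1 <- r$y
  r <- cbr_f(net, tape, "down2", s1, 1L, stride = 2L, train = train); tape <- r$tape
  r <- res_f(net, tape, "enc2", r$y, 4L * b, 4L * b, train); tape <- r$tape; s2 <- r$y
  r <- cbr_f(net, tape, "down3", s2, 1L, stride = 2L, train = train); tape <- r$tape
  r <- res_f(net, tape, "enc3", r$y, 8L * b, 8L * b, train); tape <- r$tape; s3 <- r$y
  r <- cbr_f(net, tape, "down4", s3, 1L, stride = 2L, train = train); tape <- r$tape
  r <- res_f(net, tape, "bott", r$y, 16L * b, 16L * b, train); tape <- r$tape; bt <- r$y

  u3 <- concat_fwd(upsample_fwd(bt, 2L), s3)
  r <- res_f(net, tape, "dec3", u3, 24L * b, 8L * b, train); tape <- r$tape; d3 <- r$y
  a1 <- conv_fwd(net$params$aux1.W, net$params$aux1.b, d3, 1L); tape$aux1 <- a1$cache
  u2 <- concat_fwd(upsample_fwd(d3, 2L), s2)
  r <- res_f(net, tape, "dec2", u2, 12L * b, 4L * b, train); tape <- r$tape; d2 <- r$y
  a2 <- conv_fwd(net$params$aux2.W, net$params$aux2.b, d2, 1L); tape$aux2 <- a2$cache
  u1 <- concat_fwd(upsample_fwd(d2, 2L), s1)
  r <- res_f(net, tape, "dec1", u1, 6L * b, 2L * b, train); tape <- r$tape; d1 <- r$y
  a3 <- conv_fwd(net$params$aux3.W, net$params$aux3.b, d1, 1L); tape$aux3 <- a3$cache
  u0 <- concat_fwd(upsample_fwd(d1, 2L), s0)
  r <- res_f(net, tape, "dec0", u0, 3L * b, b, train); tape <- r$tape; d0 <- r$y
  hd <- conv_fwd(net$params$head.W, net$params$head.b, d0, 1L); tape$head <- hd$cache

  preds <- lapply(list(upsample_fwd(a1$y, 8L), upsample_fwd(a2$y, 4L),
                       upsample_fwd(a3$y, 2L), hd$y),
                  function(p) aperm(p, c(1, 2, 4, 3)))   # back to [H,W,2,N]
  list(preds = preds, tape = tape)
}

#' Network backward pass
#'
#' Back-propagates gradients of the four prediction heads through the whole
#' network.
#'
#' @param net a `flownet`.
#' @param tape the `tape` returned by [flownet_forward()] (with
#'   `train = TRUE`).
#' @param dpreds list of four gradient arrays matching the `preds` shapes.
#' @return Named list of parameter gradients (same names as `net$params`).
#' @export
flownet_backward <- function(net, tape, dpreds) {
  b <- net$cfg$base_channels
  dpreds <- lapply(dpreds, function(p) aperm(p, c(1, 2, 4, 3)))  # channel-last
  grads <- list()

  hb <- conv_bwd(tape$head, dpreds[[4]])
  grads$head.W <- hb$dW; grads$head.b <- hb$db
  r <- res_b(net, tape, grads, "dec0", hb$dx); grads <- r$grads
  sp <- concat_bwd(r$dx, 2L * b)
  ds0 <- sp$db
  dd1 <- upsample_bwd(sp$da, 2L)

  a3b <- conv_bwd(tape$aux3, upsample_bwd(dpreds[[3]], 2L))
  grads$aux3.W <- a3b$dW; grads$aux3.b <- a3b$db
  dd1 <- dd1 + a3b$dx
  r <- res_b(net, tape, grads, "dec1", dd1); grads <- r$grads
  sp <- concat_bwd(r$dx, 4L * b)
  ds1 <- sp$db
  dd2 <- upsample_bwd(sp$da, 2L)

  a2b <- conv_bwd(tape$aux2, upsample_bwd(dpreds[[2]], 4L))
  grads$aux2.W <- a2b$dW; grads$aux2.b <- a2b$db
  dd2 <- dd2 + a2b$dx
  r <- res_b(net, tape, grads, "dec2", dd2); grads <- r$grads
  sp <- concat_bwd(r$dx, 8L * b)
  ds2 <- sp$db
  dd3 <- upsample_bwd(sp$da, 2L)

  a1b <- conv_bwd(tape$aux1, upsample_bwd(dpreds[[1]], 8L))
  grads$aux1.W <- a1b$dW; grads$aux1.b <- a1b$db
  dd3 <- dd3 + a1b$dx
  r <- res_b(net, tape, grads, "dec3", dd3); grads <- r$grads
  sp <- concat_bwd(r$dx, 16L * b)
  ds3 <- sp$db
  dbt <- upsample_bwd(sp$da, 2L)

  r <- res_b(net, tape, grads, "bott", dbt); grads <- r$grads
  r <- cbr_b(net, tape, r$grads, "down4", r$dx); grads <- r$grads
  r <- res_b(net, tape, grads, "enc3", r$dx + ds3); grads <- r$grads
  r <- cbr_b(net, tape, r$grads, "down3", r$dx); grads <- r$grads
  r <- res_b(net, tape, grads, "enc2", r$dx + ds2); grads <- r$grads
  r <- cbr_b(net, tape, r$grads, "down2", r$dx); grads <- r$grads
  r <- res_b(net, tape, grads, "enc1", r$dx + ds1); grads <- r$grads
  dp <- maxpool_bwd(tape$pool, r$dx)
  r <- res_b(net, tape, grads, "enc0", dp + ds0); grads <- r$grads
  r <- cbr_b(net, tape, r$grads, "stem", r$dx); grads <- r$grads
  grads
}

#' Predict displacements for a batch of input windows
#'
#' Runs the network in evaluation mode (running batch-norm statistics) and
#' returns the final head only, with out-of-mask pixels zeroed when a mask is
#' supplied.
#'
#' @param net a trained `flownet`.
#' @param x `[H, W, window, N]` (or single-sample `[H, W, window]`) input.
#' @param mask optional `[H, W]` or `[H, W, N]` mask applied to the output.
#' @return Array `[H, W, 2, N]` of predicted displacements (px/frame).
#' @export
flownet_predict <- function(net, x, mask = NULL) {
  out <- flownet_forward(net, x, train = FALSE)
  pred <- out$preds[[4]]
  if (!is.null(mask)) {
    d <- dim(pred)
    maskN <- if (is.matrix(mask)) array(rep(mask > 0, d[4]), c(d[1], d[2], d[4]))
             else array(mask > 0, c(d[1], d[2], d[4]))
    m <- aperm(array(rep(as.numeric(maskN), 2L), c(d[1], d[2], d[4], 2L)), c(1, 2, 4, 3))
    pred <- pred * m
  }
  pred
}

# --- losses ------------------------------------------------------------------

as_disp_slice <- function(x) {
  if (is.list(x) && !is.null(x$dx)) {
    return(array(c(x$dx, x$dy), c(dim(x$dx), 2L)))
  }
  x
}

#' Masked end-point error
#'
#' The Euclidean distance between predicted and reference displacement
#' vectors, averaged over the pixels of the blood-pool mask:
#' `EPE = (1/M) * sum_i sqrt((dxp - dxg)^2 + (dyp - dyg)^2)`.
#'
#' @param pred,gt displacement slices: `[H, W, 2]` arrays (or lists with
#'   matrices `dx`, `dy`).
#' @param mask `[H, W]` logical/integer mask; the `M` nonzero pixels are
#'   evaluated.
#' @return Scalar EPE (same units as the inputs).
#' @export
epe_loss <- function(pred, gt, mask) {
  pred <- as_disp_slice(pred); gt <- as_disp_slice(gt)
  m <- mask > 0
  if (!any(m)) stop("degenerate input: empty mask", call. = FALSE)
  dx <- pred[, , 1][m] - gt[, , 1][m]
  dy <- pred[, , 2][m] - gt[, , 2][m]
  mean(sqrt(dx^2 + dy^2))
}

# batched EPE pooled over all masked pixels of the batch; pred/gt [H,W,2,N],
# maskN [H,W,N]
epe_batch <- function(pred, gt, maskN) {
  dx <- pred[, , 1L, , drop = FALSE] - gt[, , 1L, , drop = FALSE]
  dy <- pred[, , 2L, , drop = FALSE] - gt[, , 2L, , drop = FALSE]
  e <- as.vector(sqrt(dx * dx + dy * dy))
  m <- as.vector(maskN > 0)
  if (!any(m)) stop("degenerate input: empty mask", call. = FALSE)
  sum(e[m]) / sum(m)
}

# gradient of epe_batch wrt pred (zero where the error vector vanishes)
epe_batch_grad <- function(pred, gt, maskN) {
  dx <- pred[, , 1L, , drop = FALSE] - gt[, , 1L, , drop = FALSE]
  dy <- pred[, , 2L, , drop = FALSE] - gt[, , 2L, , drop = FALSE]
  nrm <- sqrt(dx * dx + dy * dy)
  M <- sum(maskN > 0)
  w <- array(0, dim(nrm))
  ok <- array(as.vector(maskN > 0), dim(nrm)) & (nrm > 0)
  w[ok] <- 1 / (nrm[ok] * M)
  g <- array(0, dim(pred))
  g[, , 1L, ] <- dx * w
  g[, , 2L, ] <- dy * w
  g
}

#' Deep-supervision total loss
#'
#' `Loss = EPE(G, O) + sum_c w_c * EPE(G, P_c)`: the masked EPE of the final
#' output plus weighted EPEs of the three auxiliary predictions, all against
#' the same ground truth and mask.
#'
#' @param preds list of four `[H, W, 2]` (or `[H, W, 2, N]`) predictions,
#'   auxiliaries first, final head last.
#' @param gt ground-truth displacement, same shape as each prediction.
#' @param mask `[H, W]` (or `[H, W, N]`) mask.
#' @param aux_weights numeric length 3, `(w1, w2, w3)`.
#' @return Scalar total loss.
#' @export
total_loss <- function(preds, gt, mask, aux_weights = c(0.25, 0.5, 0.75)) {
  stopifnot(length(preds) == 4L)
  gt <- as_disp_slice(gt)
  single <- length(dim(gt)) == 3L
  fix <- function(a) { a <- as_disp_slice(a); if (single) dim(a) <- c(dim(a), 1L); a }
  gt4 <- fix(gt)
  N <- dim(gt4)[4]
  maskN <- if (is.matrix(mask)) array(rep(mask, N), c(dim(mask), N)) else mask
  l <- epe_batch(fix(preds[[4]]), gt4, maskN)
  for (c_ in 1:3) l <- l + aux_weights[c_] * epe_batch(fix(preds[[c_]]), gt4, maskN)
  l
}

total_loss_grads <- function(preds, gt, maskN, aux_weights) {
  dp <- vector("list", 4L)
  for (c_ in 1:3) {
    g <- epe_batch_grad(preds[[c_]], gt, maskN)
    dp[[c_]] <- aux_weights[c_] * g
  }
  dp[[4]] <- epe_batch_grad(preds[[4]], gt, maskN)
  dp
}
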