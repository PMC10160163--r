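#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size windows per optimization step.
#' @param lr Adam learning rate.
#' @param lr_decay_factor multiplicative step decay of the learning rate
#'   (1 = constant).
#' @param lr_decay_at fraction of the epochs after which the decay is
#'   applied.
#' @param optimizer only `"adam"` is implemented.
#' @param seed seed covering weight init, batch order (and fold split when
#'   used through [cross_validate()]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, lr = 1e-3,
                         lr_decay_factor = 1, lr_decay_at = 0.6,
                         optimizer = "adam", seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0,
            lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_at > 0, lr_decay_at <= 1)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_at = lr_decay_at,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' Case-level k-fold split
#'
#' Partitions case identifiers (never individual images) into `k` folds of
#' sizes differing by at most one, deterministically under `seed`.
#'
#' @param case_ids character/integer vector of unique case identifiers.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return A tibble `(case_id, fold)` with folds `1..k`.
#' @export
split_folds <- function(case_ids, k, seed = 1L) {
  if (anyDuplicated(case_ids)) stop("duplicate case ids", call. = FALSE)
  n <- length(case_ids)
  if (k > n) stop("more folds than cases", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  # round-robin over the shuffled order: the first n %% k folds get one extra
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  tibble::tibble(case_id = case_ids, fold = fold)
}

#' Build (window, displacement, mask) training samples for one case
#'
#' Normalizes the cine over the pooled blood-pool histogram, converts the
#' reference velocities to per-frame pixel displacements, and assembles one
#' cyclic temporal window per phase.
#'
#' @param phantom a `phantom` (or any list with `cine`, `truth`, `mask`).
#' @param window input frame count (odd).
#' @return List with `x` `[H, W, window, T]`, `y` `[H, W, 2, T]`,
#'   `mask` `[H, W, T]`, `meta`.
#' @export
case_samples <- function(phantom, window = 9L) {
  k <- (window - 1L) %/% 2L
  norm <- normalize_intensities(phantom$cine, phantom$mask)$cine
  disp <- velocity_to_displacement(phantom$truth, phantom$cine$meta)
  d <- dim(norm$frames); T_ <- d[1]; H <- d[2]; W <- d[3]
  x <- array(0, c(H, W, window, T_))
  y <- array(0, c(H, W, 2L, T_))
  m <- array(0, c(H, W, T_))
  for (t in 0:(T_ - 1L)) {
    win <- temporal_window(norm, t, k)                 # [window, H, W]
    x[, , , t + 1L] <- aperm(win, c(2, 3, 1))
    y[, , 1L, t + 1L] <- disp$dx[t + 1L, , ]
    y[, , 2L, t + 1L] <- disp$dy[t + 1L, , ]
    m[, , t + 1L] <- phantom$mask$labels[t + 1L, , ]
  }
  list(x = x, y = y, mask = m, meta = phantom$cine$meta)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the network on a set of cases
#'
#' Minimizes the deep-supervision masked EPE loss over all (window,
#' displacement, mask) samples of the training cases — one sample per phase
#' per case — with Adam and shuffled mini-batches. Reproducible for a fixed
#' `train_cfg$seed`.
#'
#' @param train_cases list of phantoms/cases (see [case_samples()]).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param net optionally, an existing network to continue training.
#' @param quiet suppress per-epoch messages.
#' @return List with `net` (trained `flownet`) and `history` (tibble
#'   `(epoch, loss, epe)` of per-epoch means over training batches).
#' @export
train_fold <- function(train_cases, net_cfg = network_config(),
                       train_cfg = train_config(), net = NULL, quiet = TRUE) {
  stopifnot(length(train_cases) >= 1L)
  samples <- lapply(train_cases, case_samples, window = net_cfg$window)
  T_each <- vapply(samples, function(s) dim(s$x)[4], integer(1))
  index <- do.call(rbind, lapply(seq_along(samples), function(i)
    cbind(case = i, t = seq_len(T_each[i]))))
  if (is.null(net)) net <- build_network(net_cfg)
  set.seed(train_cfg$seed)
  opt <- adam_init(net$params)
  n <- nrow(index)
  bs <- min(train_cfg$batch_size, n)
  history <- data.frame(epoch = integer(0), loss = numeric(0), epe = numeric(0))
  for (ep in seq_len(train_cfg$epochs)) {
    lr_ep <- train_cfg$lr *
      if (ep > train_cfg$lr_decay_at * train_cfg$epochs) train_cfg$lr_decay_factor else 1
    ord <- sample.int(n)
    losses <- c(); epes <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- array(0, c(dim(samples[[1]]$x)[1:3], length(idx)))
      yb <- array(0, c(dim(samples[[1]]$y)[1:3], length(idx)))
      mb <- array(0, c(dim(samples[[1]]$mask)[1:2], length(idx)))
      for (j in seq_along(idx)) {
        ci <- index[idx[j], 1]; ti <- index[idx[j], 2]
        xb[, , , j] <- samples[[ci]]$x[, , , ti]
        yb[, , , j] <- samples[[ci]]$y[, , , ti]
        mb[, , j] <- samples[[ci]]$mask[, , ti]
      }
      fw <- flownet_forward(net, xb, train = TRUE)
      loss <- total_loss(fw$preds, yb, mb, net$cfg$aux_weights)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep, call. = FALSE)
      dpreds <- total_loss_grads(fw$preds, yb, mb, net$cfg$aux_weights)
      grads <- flownet_backward(net, fw$tape, dpreds)
      upd <- adam_step(net$params, grads, opt, lr_ep)
      net$params <- upd$params; opt <- upd$state
      losses <- c(losses, loss)
      epes <- c(epes, epe_batch(fw$preds[[4]], yb, mb))
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = mean(losses), epe = mean(epes)))
    if (!quiet) message(sprintf("epoch %d  loss %.4f  epe %.4f",
                                ep, mean(losses), mean(epes)))
  }
  list(net = net, history = tibble::as_tibble(history))
}

#' Predict the displacement field of a whole case
#'
#' @param net trained `flownet`.
#' @param phantom case providing cine and mask.
#' @param batch phases per forward pass.
#' @return A [displacement_field()] `[T, H, W]` with out-of-mask pixels zero.
#' @export
predict_case <- function(net, phantom, batch = 10L) {
  s <- case_samples(phantom, window = net$cfg$window)
  d <- dim(s$x); T_ <- d[4]; H <- d[1]; W <- d[2]
  dx <- array(0, c(T_, H, W)); dy <- array(0, c(T_, H, W))
  for (start in seq(1L, T_, by = batch)) {
    idx <- start:min(start + batch - 1L, T_)
    pred <- flownet_predict(net, s$x[, , , idx, drop = FALSE], mask = s$mask[, , idx])
    for (j in seq_along(idx)) {
      dx[idx[j], , ] <- pred[, , 1L, j]
      dy[idx[j], , ] <- pred[, , 2L, j]
    }
  }
  displacement_field(dx, dy)
}

#' Case-level k-fold cross-validated training
#'
#' Trains one network per fold on all other folds' cases and predicts each
#' case exactly once, with the model whose training set excluded it. The
#' out-of-fold displacement predictions are also converted to velocity fields
#' for downstream evaluation.
#'
#' @param cases named list of phantoms/cases.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param k number of folds.
#' @param checkpoint_dir optional directory; when given, each fold's trained
#'   network is saved under `fold<k>/` via [save_network()].
#' @param quiet suppress progress messages.
#' @return An object of class `cv_result`: list with `folds` (tibble),
#'   `predictions` (per case: `disp`, `flow`, `fold`), `histories` (per
#'   fold).
#' @export
cross_validate <- function(cases, net_cfg = network_config(),
                           train_cfg = train_config(), k = 5L,
                           checkpoint_dir = NULL, quiet = TRUE) {
  ids <- names(cases)
  if (is.null(ids)) ids <- as.character(seq_along(cases))
  folds <- split_folds(ids, k, seed = train_cfg$seed)
  predictions <- stats::setNames(vector("list", length(cases)), ids)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- folds$case_id[folds$fold != f]
    test_ids <- folds$case_id[folds$fold == f]
    stopifnot(length(intersect(train_ids, test_ids)) == 0L)
    fit <- train_fold(cases[train_ids], net_cfg, train_cfg, quiet = quiet)
    histories[[f]] <- fit$history
    if (!is.null(checkpoint_dir))
      save_network(fit$net, file.path(checkpoint_dir, sprintf("fold%d", f)))
    for (id in test_ids) {
      disp <- predict_case(fit$net, cases[[id]])
      flow <- displacement_to_velocity(disp, cases[[id]]$cine$meta)
      predictions[[id]] <- list(disp = disp, flow = flow, fold = f)
    }
  }
  structure(list(folds = folds, predictions = predictions, histories = histories,
                 k = k), class = "cv_result")
}

#' EPE of the zero-displacement baseline
#'
#' Mean displacement magnitude over masked pixels, pooled over phases — the
#' error a predictor that always outputs zero motion would achieve.
#'
#' @param disp ground-truth [displacement_field()].
#' @param mask a [blood_pool_mask()].
#' @return Scalar baseline EPE (px/frame).
#' @export
zero_baseline_epe <- function(disp, mask) {
  m <- mask$labels > 0L
  mean(sqrt(disp$dx[m]^2 + disp$dy[m]^2))
}
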