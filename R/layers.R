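# Neural-network layer primitives.
#
# Activations are stored channel-last, [H, W, N, C], so that flattening to
# the (H*W*N) x C matrix form needed by im2col + GEMM is a reshape, not a
# transpose; the heavy lifting then runs in BLAS. Every layer has a
# hand-derived backward pass. Weight matrices for a k x k convolution are
# (k*k*Cin) x Cout with rows ordered offset-major (column-major over the
# kernel window), input-channel-minor — the ordering im2col produces.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

# pixel row indices into the padded (Hp*Wp) x (N*C) matrix for each kernel
# offset; list of k*k integer vectors of length H*W
conv_offsets <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  out <- vector("list", k * k)
  q <- 1L
  for (dj in 1:k) for (di in 1:k) {
    out[[q]] <- as.vector(outer(di + 0:(H - 1L), (dj - 1L + 0:(W - 1L)) * Hp, "+"))
    q <- q + 1L
  }
  out
}

# k x k same-padding convolution as k^2 row-gathered GEMMs; x is [H,W,N,C],
# W_ is (k*k*C) x Cout with rows offset-major, input-channel-minor
conv_fwd <- function(W_, b_, x, k = 3L, stride = 1L) {
  d <- dim(x)
  if (stride > 1L) {
    x <- x[seq(1L, d[1], stride), seq(1L, d[2], stride), , , drop = FALSE]
    d <- dim(x)
  }
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  cout <- ncol(W_)
  if (k == 1L) {
    ym <- as_mat(x) %*% W_
    cache <- list(xp = x, dims = d, k = k, stride = stride, W = W_)
  } else {
    p <- (k - 1L) %/% 2L
    xp <- array(0, c(H + 2L * p, W + 2L * p, N, C))
    xp[p + (1:H), p + (1:W), , ] <- x
    dim(xp) <- c((H + 2L * p) * (W + 2L * p), N * C)
    offs <- conv_offsets(H, W, k)
    ym <- matrix(0, H * W * N, cout)
    xos <- vector("list", k * k)
    for (q in seq_len(k * k)) {
      xo <- xp[offs[[q]], ]
      dim(xo) <- c(H * W * N, C)
      xos[[q]] <- xo
      ym <- ym + xo %*% W_[((q - 1L) * C + 1L):(q * C), , drop = FALSE]
    }
    cache <- list(xos = xos, offs = offs, npad = nrow(xp), dims = d, k = k,
                  stride = stride, W = W_)
  }
  if (!is.null(b_)) ym <- sweep(ym, 2L, b_, "+")
  dim(ym) <- c(H, W, N, cout)
  list(y = ym, cache = cache)
}

conv_bwd <- function(cache, dy) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- cache$k
  dym <- as_mat(dy)
  db <- colSums(dym)
  if (k == 1L) {
    dW <- crossprod(as_mat(cache$xp), dym)
    dx <- tcrossprod(dym, cache$W)
    dim(dx) <- d
  } else {
    p <- (k - 1L) %/% 2L
    offs <- cache$offs
    dW <- matrix(0, nrow(cache$W), ncol(cache$W))
    dxp <- matrix(0, cache$npad, N * C)
    for (q in seq_len(k * k)) {
      rows <- ((q - 1L) * C + 1L):(q * C)
      dW[rows, ] <- crossprod(cache$xos[[q]], dym)
      dxo <- tcrossprod(dym, cache$W[rows, , drop = FALSE])
      dim(dxo) <- c(H * W, N * C)
      dxp[offs[[q]], ] <- dxp[offs[[q]], ] + dxo
    }
    dim(dxp) <- c(H + 2L * p, W + 2L * p, N, C)
    dx <- dxp[p + (1:H), p + (1:W), , , drop = FALSE]
  }
  if (cache$stride > 1L) {
    s <- cache$stride
    full <- array(0, c(H * s, W * s, N, C))
    full[seq(1L, H * s, s), seq(1L, W * s, s), , ] <- dx
    dx <- full
  }
  list(dx = dx, dW = dW, db = db)
}

# batch normalization over (H, W, N) per channel
bn_fwd <- function(gamma, beta, x, train, rm, rv, mom = 0.1, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2] * d[3]
  xm <- as_mat(x)
  if (train) {
    mu <- colMeans(xm)
    var_ <- colMeans(xm * xm) - mu * mu
    rm <- (1 - mom) * rm + mom * mu
    rv <- (1 - mom) * rv + mom * var_
  } else {
    mu <- rm; var_ <- rv
  }
  invstd <- 1 / sqrt(var_ + eps)
  xhat <- sweep(xm, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, invstd, "*")
  y <- sweep(xhat, 2L, gamma, "*")
  y <- sweep(y, 2L, beta, "+")
  dim(y) <- d
  list(y = y, rm = rm, rv = rv,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d, m = m))
}

bn_bwd <- function(cache, dy) {
  d <- cache$dims; m <- cache$m
  dym <- as_mat(dy); xhm <- cache$xhat
  dgamma <- colSums(dym * xhm)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, cache$gamma, "*")
  # dx = invstd/m * (m*dxhat - sum_c(dxhat) - xhat * sum_c(dxhat * xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhm)
  dx <- m * dxhat
  dx <- sweep(dx, 2L, s1, "-")
  dx <- dx - sweep(xhm, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$invstd / m, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}
relu_bwd <- function(cache, dy) dy * cache

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  q <- list(x[io, jo, , , drop = FALSE], x[io, jo + 1L, , , drop = FALSE],
            x[io + 1L, jo, , , drop = FALSE], x[io + 1L, jo + 1L, , , drop = FALSE])
  y <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  # first quadrant attaining the max wins (deterministic tie-break)
  arg <- array(1L, dim(y))
  taken <- q[[1]] == y
  for (k in 2:4) {
    hit <- (q[[k]] == y) & !taken
    arg[hit] <- k
    taken <- taken | hit
  }
  list(y = y, cache = list(arg = arg, dims = d))
}

maxpool_bwd <- function(cache, dy) {
  d <- cache$dims
  dx <- array(0, d)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  arg <- cache$arg
  dx[io, jo, , ] <- dy * (arg == 1L)
  dx[io, jo + 1L, , ] <- dy * (arg == 2L)
  dx[io + 1L, jo, , ] <- dy * (arg == 3L)
  dx[io + 1L, jo + 1L, , ] <- dy * (arg == 4L)
  dx
}

upsample_fwd <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , , drop = FALSE]
}

upsample_bwd <- function(dy, f) {
  d <- dim(dy); H <- d[1] %/% f; W <- d[2] %/% f
  rest <- d[3] * d[4]
  m <- dy
  dim(m) <- c(f, H, f * W * rest)
  s1 <- colSums(m)                              # [H, f, W, rest]
  dim(s1) <- c(H, f, W * rest)
  s2 <- colSums(aperm(s1, c(2, 1, 3)))          # [H, W*rest]
  array(s2, c(H, W, d[3], d[4]))
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

concat_bwd <- function(dy, c1) {
  d <- dim(dy)
  list(da = dy[, , , seq_len(c1), drop = FALSE],
       db = dy[, , , (c1 + 1L):d[4], drop = FALSE])
}
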