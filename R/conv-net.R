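# Minimal convolutional-network engine used by the liver segmenter and the
# deep-clustering autoencoder. Batches are 4-D arrays dim = c(B, H, W, C)
# (batch-fastest, column-major), which makes every conv offset a single
# matrix multiplication. Sized for desk-scale inputs (16x16 patches, 64x64
# slices); stride-1 'same' convolutions, 2x2 average pooling, nearest x2
# upsampling, dense layers, ReLU/sigmoid. All randomness comes from the
# caller's RNG state.

nn_conv <- function(kh, kw, cin, cout, stride = 1L) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(type = "conv",
       W = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout), stride = as.integer(stride))
}

nn_dense <- function(nin, nout) {
  list(type = "dense",
       W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

nn_relu    <- function() list(type = "relu")
nn_pool2   <- function() list(type = "pool2")
nn_up2     <- function() list(type = "up2")
nn_reshape <- function(h, w, c) list(type = "reshape", dims = c(h, w, c))

# Activations are flattened to B x (H*W*C) matrices so that building the
# im2col matrix is a single C-level column subset with a cached index
# vector; the whole convolution is then one BLAS matmul against the
# unrolled kernel.
.idx_cache <- new.env(parent = emptyenv())

.offset_cols <- function(H, W, C, ph, pw, di, dj, stride = 1L) {
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  ho <- H %/% stride; wo <- W %/% stride
  rows <- (di - 1L) + seq.int(1L, by = stride, length.out = ho)
  cols <- (dj - 1L) + seq.int(1L, by = stride, length.out = wo)
  base <- rep(rows, times = wo) + Hp * rep(cols - 1L, each = ho)
  as.vector(outer(base, (seq_len(C) - 1L) * Hp * Wp, "+"))
}

# Indices of all kh*kw window shifts, offset-major (di fastest), cached.
.im2col_cols <- function(H, W, C, kh, kw, ph, pw, stride = 1L) {
  key <- paste(H, W, C, kh, kw, ph, pw, stride, sep = "_")
  idx <- .idx_cache[[key]]
  if (is.null(idx)) {
    idx <- unlist(lapply(seq_len(kw), function(dj)
      lapply(seq_len(kh), function(di)
        .offset_cols(H, W, C, ph, pw, di, dj, stride))), use.names = FALSE)
    .idx_cache[[key]] <- idx
  }
  idx
}

.pad_flat <- function(x, ph, pw) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  xp <- matrix(0, B, Hp * Wp * C)
  xp[, .offset_cols(H, W, C, ph, pw, ph + 1L, pw + 1L)] <-
    matrix(x, B, H * W * C)
  xp
}

# Unrolled kernels, rows matching the offset-major im2col column order.
.kernel_mat <- function(W, flip = FALSE) {
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  blocks <- lapply(seq_len(kw), function(dj)
    lapply(seq_len(kh), function(di) {
      if (flip)
        t(matrix(W[kh - di + 1L, kw - dj + 1L, , ], cin, cout))
      else
        matrix(W[di, dj, , ], cin, cout)
    }))
  do.call(rbind, unlist(blocks, recursive = FALSE))
}

.conv_fwd <- function(layer, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; cin <- d[4]
  kd <- dim(layer$W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  s <- if (is.null(layer$stride)) 1L else layer$stride
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  ho <- H %/% s; wo <- W %/% s
  xp <- .pad_flat(x, ph, pw)
  M <- xp[, .im2col_cols(H, W, cin, kh, kw, ph, pw, s), drop = FALSE]
  dim(M) <- c(B * ho * wo, kh * kw * cin)
  out <- M %*% .kernel_mat(layer$W)
  out <- sweep(out, 2L, layer$b, "+")
  list(out = array(out, c(B, ho, wo, cout)),
       cache = list(M = M, hw = c(H, W), cin = cin))
}

.conv_bwd <- function(layer, cache, gout, need_gx = TRUE) {
  H <- cache$hw[1]; W <- cache$hw[2]; cin <- cache$cin
  B <- dim(gout)[1]; cout <- dim(gout)[4]
  kd <- dim(layer$W); kh <- kd[1]; kw <- kd[2]
  s <- if (is.null(layer$stride)) 1L else layer$stride
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  ho <- H %/% s; wo <- W %/% s
  gmat <- matrix(gout, B * ho * wo, cout)
  gWm <- crossprod(cache$M, gmat)  # (kh*kw*cin) x cout, offset-major
  gW <- array(0, kd)
  r <- 0L
  for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    gW[di, dj, , ] <- gWm[r + seq_len(cin), , drop = FALSE]
    r <- r + cin
  }
  out <- list(gx = NULL, gW = gW, gb = colSums(gmat))
  if (!need_gx) return(out)
  if (s == 1L) {
    # input gradient = 'same' convolution of gout with the flipped kernel
    gp <- .pad_flat(gout, ph, pw)
    Mg <- gp[, .im2col_cols(H, W, cout, kh, kw, ph, pw), drop = FALSE]
    dim(Mg) <- c(B * H * W, kh * kw * cout)
    out$gx <- array(Mg %*% .kernel_mat(layer$W, flip = TRUE),
                    c(B, H, W, cin))
  } else {
    # strided: scatter-add each offset's contribution (col2im)
    Hp <- H + 2L * ph; Wp <- W + 2L * pw
    gxp <- matrix(0, B, Hp * Wp * cin)
    for (dj in seq_len(kw)) for (di in seq_len(kh)) {
      Gk <- gmat %*% t(matrix(layer$W[di, dj, , ], cin, cout))
      dim(Gk) <- NULL
      idx <- .offset_cols(H, W, cin, ph, pw, di, dj, s)
      gxp[, idx] <- gxp[, idx, drop = FALSE] +
        matrix(Gk, B, ho * wo * cin)
    }
    gx <- gxp[, .offset_cols(H, W, cin, ph, pw, ph + 1L, pw + 1L),
              drop = FALSE]
    out$gx <- array(gx, c(B, H, W, cin))
  }
  out
}

.pool2_fwd <- function(x) {
  d <- dim(x); H <- d[2]; W <- d[3]
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  out <- (x[, io, jo, , drop = FALSE] + x[, ie, jo, , drop = FALSE] +
          x[, io, je, , drop = FALSE] + x[, ie, je, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

.pool2_bwd <- function(cache, gout) {
  d <- cache; H <- d[2]; W <- d[3]
  gx <- array(0, d)
  g4 <- gout / 4
  io <- seq(1L, H, 2L); ie <- io + 1L
  jo <- seq(1L, W, 2L); je <- jo + 1L
  gx[, io, jo, ] <- g4; gx[, ie, jo, ] <- g4
  gx[, io, je, ] <- g4; gx[, ie, je, ] <- g4
  gx
}

.up2_fwd <- function(x) {
  d <- dim(x)
  out <- x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
           drop = FALSE]
  list(out = out, cache = d)
}

.up2_bwd <- function(cache, gout) {
  H2 <- dim(gout)[2]; W2 <- dim(gout)[3]
  io <- seq(1L, H2, 2L); ie <- io + 1L
  jo <- seq(1L, W2, 2L); je <- jo + 1L
  gout[, io, jo, , drop = FALSE] + gout[, ie, jo, , drop = FALSE] +
    gout[, io, je, , drop = FALSE] + gout[, ie, je, , drop = FALSE]
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv  = .conv_fwd(layer, x),
    relu  = list(out = {o <- x; o[o < 0] <- 0; o}, cache = x),
    pool2 = .pool2_fwd(x),
    up2   = .up2_fwd(x),
    sigmoid = {p <- 1 / (1 + exp(-x)); list(out = p, cache = p)},
    reshape = {
      B <- dim(x)[1]
      list(out = array(x, c(B, layer$dims)), cache = dim(x))
    },
    dense = {
      B <- dim(x)[1]
      xm <- matrix(x, B, prod(dim(x)[-1]))
      list(out = sweep(xm %*% layer$W, 2L, layer$b, "+"),
           cache = list(xm = xm, din = dim(x)))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, gout, need_gx = TRUE) {
  switch(layer$type,
    conv  = .conv_bwd(layer, cache, gout, need_gx),
    relu  = list(gx = gout * (cache > 0)),
    pool2 = list(gx = .pool2_bwd(cache, gout)),
    up2   = list(gx = .up2_bwd(cache, gout)),
    sigmoid = list(gx = gout * cache * (1 - cache)),
    reshape = list(gx = array(gout, cache)),
    dense = list(gx = array(gout %*% t(layer$W), cache$din),
                 gW = crossprod(cache$xm, gout), gb = colSums(gout)),
    stop("unknown layer type: ", layer$type))
}

nn_forward <- function(net, x) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, gout, need_input_grad = TRUE) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], gout,
                        need_gx = need_input_grad || i > 1L)
    gout <- r$gx
    grads[[i]] <- r[intersect(c("gW", "gb"), names(r))]
  }
  list(gin = gout, grads = grads)
}

# Adam with bias correction; state mirrors the layer list.
nn_adam_init <- function(net) {
  lapply(net, function(l) {
    if (is.null(l$W)) NULL else
      list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
}

nn_adam_step <- function(net, grads, state, t, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    if (is.null(state[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    net[[i]]$W <- net[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net[[i]]$b <- net[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}
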