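# Minimal CNN engine on base R matrix algebra.
#
# Layout conventions:
#   * spatial tensors are H x W x C x N arrays
#   * im2col matrices have rows ordered (row, col, sample) with the row
#     index fastest, and columns ordered (kernel-row, kernel-col, channel)
#   * fully connected activations are D x N matrices
#
# Only what the screening classifier needs is implemented: convolution,
# ReLU, 2x2 average pooling, flatten, fully connected layers, inverted
# dropout, softmax, and Adam.

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

pad_tensor <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(xp, k, stride, ho, wo) {
  d <- dim(xp)
  n <- d[4]; cin <- d[3]
  col <- matrix(0, ho * wo * n, k * k * cin)
  for (c_ in seq_len(cin)) {
    for (dj in seq_len(k)) {
      cols_j <- seq(dj, by = stride, length.out = wo)
      for (di in seq_len(k)) {
        rows_i <- seq(di, by = stride, length.out = ho)
        idx <- di + (dj - 1L) * k + (c_ - 1L) * k * k
        col[, idx] <- xp[rows_i, cols_j, c_, ]
      }
    }
  }
  col
}

conv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x); n <- d[4]
  ho <- conv_out_size(d[1], k, stride, pad)
  wo <- conv_out_size(d[2], k, stride, pad)
  xp <- pad_tensor(x, pad)
  col <- im2col(xp, k, stride, ho, wo)
  out_mat <- col %*% W
  out_mat <- out_mat + matrix(b, nrow(out_mat), length(b), byrow = TRUE)
  out <- aperm(array(out_mat, c(ho, wo, n, length(b))), c(1, 2, 4, 3))
  list(out = out, cache = list(col = col, xp_dim = dim(xp), x_dim = d,
                               k = k, stride = stride, pad = pad,
                               ho = ho, wo = wo))
}

conv_backward <- function(dout, W, cache) {
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  ho <- cache$ho; wo <- cache$wo
  n <- cache$x_dim[4]; cin <- cache$x_dim[3]
  dout_mat <- matrix(aperm(dout, c(1, 2, 4, 3)), ho * wo * n, ncol(W))
  dW <- crossprod(cache$col, dout_mat)
  db <- colSums(dout_mat)
  dcol <- tcrossprod(dout_mat, W)
  dxp <- array(0, cache$xp_dim)
  for (c_ in seq_len(cin)) {
    for (dj in seq_len(k)) {
      cols_j <- seq(dj, by = stride, length.out = wo)
      for (di in seq_len(k)) {
        rows_i <- seq(di, by = stride, length.out = ho)
        idx <- di + (dj - 1L) * k + (c_ - 1L) * k * k
        dxp[rows_i, cols_j, c_, ] <- dxp[rows_i, cols_j, c_, ] +
          array(dcol[, idx], c(ho, wo, n))
      }
    }
  }
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(cache$x_dim[1]), pad + seq_len(cache$x_dim[2]), , ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  out <- (x[i1, j1, , , drop = FALSE] + x[i1, j2, , , drop = FALSE] +
          x[i2, j1, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpool2_backward <- function(dout, d) {
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  g <- dout / 4
  dx[i1, j1, , ] <- g; dx[i1, j2, , ] <- g
  dx[i2, j1, , ] <- g; dx[i2, j2, , ] <- g
  dx
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# He-normal initialization for one layer's weights.
init_layer_params <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$k^2 * layer$cin
    layer$W <- matrix(rnorm(layer$k^2 * layer$cin * layer$cout,
                            sd = sqrt(2 / fan_in)),
                      layer$k^2 * layer$cin, layer$cout)
    layer$b <- rep(0, layer$cout)
  } else if (layer$type == "fc") {
    layer$W <- matrix(rnorm(layer$din * layer$dout,
                            sd = sqrt(2 / layer$din)),
                      layer$din, layer$dout)
    layer$b <- rep(0, layer$dout)
  }
  layer
}

# Backbone architecture specs. Each is a list of layer descriptors; the
# two dropout layers always sit on the last two fully connected (hidden)
# layers, after their ReLU.
backbone_layers <- function(backbone, input_shape, dropout_rate,
                            head_widths = NULL) {
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  conv <- function(k, ci, co, s, p) list(type = "conv", k = k, cin = ci,
                                         cout = co, stride = s, pad = p)
  relu <- list(type = "relu")
  pool <- list(type = "avgpool2")
  drop <- list(type = "dropout", rate = dropout_rate)
  fc <- function(di, do) list(type = "fc", din = di, dout = do)
  if (is.null(head_widths)) {
    head_widths <- switch(backbone, tiny_cnn = c(32, 8),
                          mobilenet_like = c(64, 32),
                          vgg_like = c(128, 64))
  }
  w1 <- head_widths[1]; w2 <- head_widths[2]
  # The two dropout layers sit on the two hidden fully connected layers
  # of every backbone. The tiny backbone keeps this head narrow: with
  # few units per layer, dropping half of them genuinely perturbs
  # borderline decisions, so the Monte-Carlo passes carry a usable
  # disagreement signal at desk scale (wide heads average the dropout
  # noise away).
  head <- function(din) list(list(type = "flatten"),
                             fc(din, w1), relu, drop,
                             fc(w1, w2), relu, drop,
                             fc(w2, 2))
  layers <- switch(
    backbone,
    tiny_cnn = c(list(
      conv(5, cin, 8, 2, 2), relu, pool,
      conv(3, 8, 16, 1, 1), relu, pool),
      head((h / 8) * (w / 8) * 16)),
    mobilenet_like = c(list(
      conv(3, cin, 8, 2, 1), relu,
      conv(3, 8, 8, 1, 1), relu, conv(1, 8, 16, 1, 0), relu, pool,
      conv(3, 16, 16, 1, 1), relu, conv(1, 16, 32, 1, 0), relu, pool),
      head((h / 8) * (w / 8) * 32)),
    vgg_like = c(list(
      conv(3, cin, 8, 1, 1), relu, conv(3, 8, 8, 1, 1), relu, pool,
      conv(3, 8, 16, 1, 1), relu, conv(3, 16, 16, 1, 1), relu, pool,
      conv(3, 16, 32, 1, 1), relu, conv(3, 32, 32, 1, 1), relu, pool),
      head((h / 8) * (w / 8) * 32)),
    stop("unknown backbone: ", backbone))
  layers
}

# Full forward pass. `dropout_active` controls stochastic dropout (TRUE
# during training and during Monte-Carlo inference passes); when FALSE,
# dropout layers are the identity (inverted dropout needs no rescale).
# Inputs in [0,1] are centred to [-1,1] first (zero-mean inputs match
# the He initialization assumptions; the centring is affine so it does
# not affect gradients beyond a constant factor).
nn_forward <- function(layers, x, dropout_active = FALSE,
                       keep_caches = FALSE) {
  x <- 2 * x - 1
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- conv_forward(x, ly$W, ly$b, ly$k, ly$stride, ly$pad)
      x <- r$out
      if (keep_caches) caches[[i]] <- r$cache
    } else if (ly$type == "relu") {
      # leaky ReLU (slope 0.01): keeps narrow layers from dying under
      # heavy dropout
      if (keep_caches) caches[[i]] <- list(mask = x > 0)
      x <- pmax(x, 0) + 0.01 * pmin(x, 0)
    } else if (ly$type == "avgpool2") {
      r <- avgpool2_forward(x)
      x <- r$out
      if (keep_caches) caches[[i]] <- r$cache
    } else if (ly$type == "flatten") {
      if (keep_caches) caches[[i]] <- dim(x)
      n <- dim(x)[4]
      x <- matrix(x, length(x) / n, n)
    } else if (ly$type == "fc") {
      if (keep_caches) caches[[i]] <- list(x = x)
      x <- crossprod(ly$W, x) + ly$b
    } else if (ly$type == "dropout") {
      if (dropout_active && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) < keep) / keep
        x <- x * mask
        if (keep_caches) caches[[i]] <- list(mask = mask)
      } else if (keep_caches) {
        caches[[i]] <- list(mask = NULL)
      }
    }
  }
  list(logits = x, probs = softmax_cols(x), caches = caches)
}

# Backward pass from a gradient on the logits; returns per-layer
# parameter gradients.
nn_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dx <- dlogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- conv_backward(dx, ly$W, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dx <- r$dx
    } else if (ly$type == "relu") {
      dx <- dx * ifelse(caches[[i]]$mask, 1, 0.01)
    } else if (ly$type == "avgpool2") {
      dx <- avgpool2_backward(dx, caches[[i]])
    } else if (ly$type == "flatten") {
      dx <- array(dx, caches[[i]])
    } else if (ly$type == "fc") {
      xin <- caches[[i]]$x
      grads[[i]] <- list(dW = tcrossprod(xin, dx), db = rowSums(dx))
      dx <- ly$W %*% dx
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) dx <- dx * caches[[i]]$mask
    }
  }
  grads
}

# One Adam update over all parameterized layers.
adam_step <- function(layers, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (p in c("W", "b")) {
      g <- if (p == "W") grads[[i]]$dW else grads[[i]]$db
      key <- paste0(i, p)
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- g * 0
        opt$v[[key]] <- g * 0
      }
      opt$m[[key]] <- b1 * opt$m[[key]] + (1 - b1) * g
      opt$v[[key]] <- b2 * opt$v[[key]] + (1 - b2) * g^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + eps)
    }
  }
  list(layers = layers, opt = opt)
}
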