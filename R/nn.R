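# Minimal CNN engine: conv (3x3, stride 1, same padding) + ReLU, 2x2 max
# pooling, dense layers, softmax with class-weighted cross-entropy, Adam.
# Batches are H x W x C x N arrays; convolutions run as im2col gathers
# followed by one BLAS matrix product, with the exact transpose scatter on
# the backward pass. All gradients are checked against finite differences
# in the test suite.

# Precompute the im2col gather index for one padded sample:
# (Ho*Wo) x (k*k*C) linear indices into an (Hp, Wp, C) array.
conv_gather_idx <- function(H, W, C, k, pad) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  prow <- outer(oi, ki - 1L, "+")              # (HW) x (k*k)
  pcol <- outer(oj, kj - 1L, "+")
  lin <- prow + (pcol - 1L) * Hp               # within one channel plane
  kk <- k * k
  idx <- matrix(rep(lin, C), H * W, kk * C)
  chan_off <- rep((seq_len(C) - 1L) * Hp * Wp, each = kk)
  idx + matrix(chan_off, H * W, kk * C, byrow = TRUE)
}

pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

layer_conv <- function(filters, k = 3L, activation = "relu") {
  structure(list(type = "conv", filters = as.integer(filters),
                 k = as.integer(k), pad = (k - 1L) %/% 2L,
                 activation = activation),
            class = "nn_layer")
}
layer_pool <- function() structure(list(type = "pool"), class = "nn_layer")
layer_flatten <- function() {
  structure(list(type = "flatten"), class = "nn_layer")
}
layer_dense <- function(units, activation = "linear") {
  structure(list(type = "dense", units = as.integer(units),
                 activation = activation),
            class = "nn_layer")
}

# Instantiate parameters for a layer spec list given the input shape
# (H, W, C) or feature length. He-normal initialisation from the ambient
# RNG stream (callers seed it).
init_layers <- function(spec, input_shape) {
  layers <- list()
  shape <- input_shape
  for (s in spec) {
    l <- unclass(s)
    if (l$type == "conv") {
      fan_in <- l$k * l$k * shape[3]
      l$W <- matrix(stats::rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                    fan_in, l$filters)
      l$b <- numeric(l$filters)
      l$input_shape <- shape
      l$idx <- conv_gather_idx(shape[1], shape[2], shape[3], l$k, l$pad)
      shape <- c(shape[1], shape[2], l$filters)
    } else if (l$type == "pool") {
      if (shape[1] %% 2L || shape[2] %% 2L) {
        stop("max-pool needs even input dims, got ",
             paste(shape[1:2], collapse = "x"), call. = FALSE)
      }
      l$input_shape <- shape
      shape <- c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
    } else if (l$type == "flatten") {
      l$input_shape <- shape
      shape <- prod(shape)
    } else if (l$type == "dense") {
      fan_in <- shape[1]
      if (length(shape) != 1L) {
        stop("dense layer needs flattened input", call. = FALSE)
      }
      l$W <- matrix(stats::rnorm(fan_in * l$units, sd = sqrt(2 / fan_in)),
                    fan_in, l$units)
      l$b <- numeric(l$units)
      l$input_shape <- shape
      shape <- l$units
    }
    layers[[length(layers) + 1L]] <- l
  }
  attr(layers, "output_shape") <- shape
  layers
}

forward_conv <- function(l, x) {
  d <- dim(x)
  N <- d[4]
  xp <- pad_batch(x, l$pad)
  dim(xp) <- c(prod(dim(xp)[1:3]), N)
  HW <- d[1] * d[2]
  kkC <- ncol(l$idx)
  M <- xp[as.vector(l$idx), , drop = FALSE]
  dim(M) <- c(HW, kkC, N)
  M <- aperm(M, c(1L, 3L, 2L))
  dim(M) <- c(HW * N, kkC)
  Y <- M %*% l$W
  Y <- sweep(Y, 2L, l$b, "+")
  if (identical(l$activation, "relu")) {
    mask <- Y > 0
    Y <- Y * mask
  } else {
    mask <- NULL
  }
  dim(Y) <- c(HW, N, l$filters)
  out <- aperm(Y, c(1L, 3L, 2L))
  dim(out) <- c(d[1], d[2], l$filters, N)
  list(out = out, cache = list(M = M, mask = mask, dims = d))
}

backward_conv <- function(l, dout, cache) {
  d <- cache$dims
  N <- d[4]; HW <- d[1] * d[2]
  dY <- dout
  dim(dY) <- c(HW, l$filters, N)
  dY <- aperm(dY, c(1L, 3L, 2L))
  dim(dY) <- c(HW * N, l$filters)
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  dWmat <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, l$W)              # (HW*N) x kkC
  dim(dM) <- c(HW, N, ncol(l$idx))
  Hp <- d[1] + 2L * l$pad; Wp <- d[2] + 2L * l$pad
  dxp <- matrix(0, Hp * Wp * d[3], N)
  for (c_ in seq_len(ncol(l$idx))) {
    ii <- l$idx[, c_]
    dxp[ii, ] <- dxp[ii, ] + dM[, , c_]
  }
  dim(dxp) <- c(Hp, Wp, d[3], N)
  dx <- if (l$pad > 0L) {
    dxp[l$pad + seq_len(d[1]), l$pad + seq_len(d[2]), , , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dW = dWmat, db = db)
}

forward_pool <- function(l, x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; dd <- x[i2, j2, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # route gradient to the first element attaining the max (fixed order)
  wa <- a == m
  wb <- (b == m) & !wa
  wc <- (cc == m) & !wa & !wb
  wd <- !wa & !wb & !wc
  list(out = m, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dims = d))
}

backward_pool <- function(l, dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
  dx[i1, j1, , ] <- dout * cache$wa
  dx[i2, j1, , ] <- dx[i2, j1, , , drop = FALSE] + dout * cache$wb
  dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + dout * cache$wc
  dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + dout * cache$wd
  dx
}

forward_layers <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- forward_conv(l, x); x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "pool") {
      r <- forward_pool(l, x); x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- d
      dim(x) <- c(prod(d[1:3]), d[4])
      x <- t(x)                      # N x features
    } else if (l$type == "dense") {
      z <- x %*% l$W
      z <- sweep(z, 2L, l$b, "+")
      if (identical(l$activation, "relu")) {
        mask <- z > 0
        z <- z * mask
        caches[[i]] <- list(x = x, mask = mask)
      } else {
        caches[[i]] <- list(x = x, mask = NULL)
      }
      x <- z
    }
  }
  list(out = x, caches = caches)
}

backward_layers <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      cache <- caches[[i]]
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      grads[[i]] <- list(dW = crossprod(cache$x, dout), db = colSums(dout))
      dout <- tcrossprod(dout, l$W)
    } else if (l$type == "flatten") {
      d <- caches[[i]]
      dout <- t(dout)
      dim(dout) <- d
    } else if (l$type == "pool") {
      dout <- backward_pool(l, dout, caches[[i]])
    } else if (l$type == "conv") {
      g <- backward_conv(l, dout, caches[[i]])
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dout <- g$dx
    }
  }
  list(grads = grads, dx = dout)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean over the batch of w[class(i)] * cross-entropy(i); gradient w.r.t.
# logits is w_i * (p_i - y_i) / N.
weighted_ce <- function(logits, classes, class_w) {
  N <- nrow(logits)
  p <- softmax_rows(logits)
  ii <- cbind(seq_len(N), classes + 1L)
  w <- class_w[classes + 1L]
  loss <- mean(w * -log(pmax(p[ii], 1e-12)))
  dlogits <- p
  dlogits[ii] <- dlogits[ii] - 1
  dlogits <- dlogits * (w / N)
  list(loss = loss, dlogits = dlogits, prob = p)
}

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in c("W", "b")) {
      key <- paste0("l", i, nm)
      gv <- if (nm == "W") g$dW else g$db
      st <- state[[key]]
      if (is.null(st)) st <- list(m = gv * 0, v = gv * 0)
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv^2
      state[[key]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  layers
}

layer_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0 else length(l$W) + length(l$b)
  }, numeric(1)))
}

layer_flops <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$type == "conv") {
      2 * l$input_shape[1] * l$input_shape[2] * l$k * l$k *
        l$input_shape[3] * l$filters
    } else if (l$type == "dense") {
      2 * l$input_shape[1] * l$units
    } else {
      0
    }
  }, numeric(1)))
}
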