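# Neural-network primitives, authored in base R + BLAS.
#
# No deep-learning framework is available to (or shipped with) this package,
# so the 3D convolution stack is implemented here directly: conv3d via
# im2col + matrix multiply, batch normalization, ReLU, 2x max pooling,
# dense layers and inverted dropout, each with an exact backward pass.
#
# Activation layout conventions:
#   spatial tensors: matrix V x (C*N), V = prod(spatial shape), column index
#                    (n-1)*C + c (channel fastest);
#   dense tensors:   matrix N x F.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# 27-neighborhood gather table for same-padding 3x3x3 convolution.
# Out-of-bounds neighbors point at a zero pad row (V+1). Offset order is
# dx fastest, so the center tap sits at offset column 14.
make_conv_nbr <- function(shape) {
  d <- shape
  v <- prod(d)
  g <- grid_coords(d)
  nbr <- matrix(v + 1L, nrow = v, ncol = 27L)
  j <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    j <- j + 1L
    nx <- g$x + dx; ny <- g$y + dy; nz <- g$z + dz
    ok <- nx >= 0L & nx < d[1] & ny >= 0L & ny < d[2] & nz >= 0L & nz < d[3]
    idx <- 1L + nx + d[1] * (ny + d[2] * nz)
    nbr[ok, j] <- idx[ok]
  }
  nbr
}

CONV_CENTER_OFFSET <- 14L

# 2x2x2 max-pool child table; odd trailing planes are dropped (floor shape).
make_pool_idx <- function(shape) {
  d <- shape
  e <- pmax(1L, as.integer(floor(d / 2)))
  g <- grid_coords(e)
  idx <- matrix(0L, nrow = prod(e), ncol = 8L)
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    o <- o + 1L
    nx <- pmin(2L * g$x + dx, d[1] - 1L)
    ny <- pmin(2L * g$y + dy, d[2] - 1L)
    nz <- pmin(2L * g$z + dz, d[3] - 1L)
    idx[, o] <- 1L + nx + d[1] * (ny + d[2] * nz)
  }
  list(idx = idx, shape_out = e)
}

layer_conv <- function(shape, c_in, c_out) {
  fan_in <- 27 * c_in
  list(kind = "conv",
       W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = c_out),
       b = numeric(c_out),
       c_in = c_in, c_out = c_out, shape = shape,
       nbr = make_conv_nbr(shape))
}

layer_bn3d <- function(c) {
  list(kind = "bn3d", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), c = c)
}

layer_relu <- function(block = NA_integer_) list(kind = "relu", block = block)

layer_pool <- function(shape, c) {
  p <- make_pool_idx(shape)
  list(kind = "pool", idx = p$idx, shape_in = shape, shape_out = p$shape_out,
       c = c)
}

layer_flatten <- function(shape, c) list(kind = "flatten", shape = shape, c = c)

layer_dense <- function(f_in, f_out, init = c("he", "glorot")) {
  init <- match.arg(init)
  sd <- if (init == "he") sqrt(2 / f_in) else sqrt(1 / f_in)
  list(kind = "dense",
       W = matrix(stats::rnorm(f_in * f_out, sd = sd), f_in, f_out),
       b = numeric(f_out))
}

layer_bn1d <- function(f) {
  list(kind = "bn1d", gamma = rep(1, f), beta = numeric(f),
       run_mean = numeric(f), run_var = rep(1, f))
}

layer_dropout <- function(rate) list(kind = "dropout", rate = rate)

bycol <- function(vals, nrow, ncol) matrix(vals, nrow, ncol, byrow = TRUE)

layer_forward <- function(layer, x, n, training) {
  switch(layer$kind,
    conv = {
      v <- prod(layer$shape)
      cn <- layer$c_in * n
      xp <- rbind(x, 0)
      p <- xp[as.vector(layer$nbr), , drop = FALSE]     # (V*27) x (C*N)
      dim(p) <- c(v, 27L, layer$c_in, n)
      p <- aperm(p, c(1, 4, 2, 3))
      dim(p) <- c(v * n, 27L * layer$c_in)
      y <- p %*% layer$W
      y <- y + bycol(layer$b, nrow(y), ncol(y))
      dim(y) <- c(v, n, layer$c_out)
      y <- aperm(y, c(1, 3, 2))
      dim(y) <- c(v, layer$c_out * n)
      list(y = y, cache = list(p = p), layer = layer)
    },
    bn3d = {
      cc <- layer$c
      chmap <- rep(seq_len(cc), n)
      if (training) {
        m <- nrow(x) * n
        cs <- rowsum(colSums(x), chmap)
        css <- rowsum(colSums(x * x), chmap)
        mu <- as.numeric(cs) / m
        va <- pmax(as.numeric(css) / m - mu^2, 0)
        scale <- 1 / sqrt(va + BN_EPS)
        xhat <- (x - bycol(mu[chmap], nrow(x), ncol(x))) *
          bycol(scale[chmap], nrow(x), ncol(x))
        y <- xhat * bycol(layer$gamma[chmap], nrow(x), ncol(x)) +
          bycol(layer$beta[chmap], nrow(x), ncol(x))
        layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * mu
        layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * va
        list(y = y, cache = list(xhat = xhat, scale = scale, chmap = chmap,
                                 m = m, training = TRUE), layer = layer)
      } else {
        scale <- 1 / sqrt(layer$run_var + BN_EPS)
        a <- (layer$gamma * scale)[chmap]
        b <- (layer$beta - layer$gamma * scale * layer$run_mean)[chmap]
        y <- x * bycol(a, nrow(x), ncol(x)) + bycol(b, nrow(x), ncol(x))
        list(y = y, cache = list(scale = scale, chmap = chmap,
                                 training = FALSE), layer = layer)
      }
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask), layer = layer)
    },
    pool = {
      cn <- ncol(x)
      best <- x[layer$idx[, 1], , drop = FALSE]
      besto <- matrix(1L, nrow(best), cn)
      for (o in 2:8) {
        cand <- x[layer$idx[, o], , drop = FALSE]
        m <- cand > best
        best[m] <- cand[m]
        besto[m] <- o
      }
      list(y = best, cache = list(besto = besto), layer = layer)
    },
    flatten = {
      v <- prod(layer$shape)
      dim(x) <- c(v, layer$c, n)
      y <- aperm(x, c(3, 1, 2))
      dim(y) <- c(n, v * layer$c)
      list(y = y, cache = NULL, layer = layer)
    },
    dense = {
      y <- x %*% layer$W
      y <- y + bycol(layer$b, nrow(y), ncol(y))
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn1d = {
      if (training) {
        m <- nrow(x)
        mu <- colMeans(x)
        va <- pmax(colMeans(x * x) - mu^2, 0)
        scale <- 1 / sqrt(va + BN_EPS)
        xhat <- (x - bycol(mu, m, ncol(x))) * bycol(scale, m, ncol(x))
        y <- xhat * bycol(layer$gamma, m, ncol(x)) + bycol(layer$beta, m, ncol(x))
        layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * mu
        layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * va
        list(y = y, cache = list(xhat = xhat, scale = scale, m = m,
                                 training = TRUE), layer = layer)
      } else {
        scale <- 1 / sqrt(layer$run_var + BN_EPS)
        a <- layer$gamma * scale
        b <- layer$beta - a * layer$run_mean
        y <- x * bycol(a, nrow(x), ncol(x)) + bycol(b, nrow(x), ncol(x))
        list(y = y, cache = list(scale = scale, training = FALSE),
             layer = layer)
      }
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) < keep) / keep
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(y = x, cache = list(mask = NULL), layer = layer)
      }
    },
    stopf("unknown layer kind '%s'", layer$kind)
  )
}

layer_backward <- function(layer, dy, cache, n) {
  switch(layer$kind,
    conv = {
      v <- prod(layer$shape)
      dim(dy) <- c(v, layer$c_out, n)
      dym <- aperm(dy, c(1, 3, 2))
      dim(dym) <- c(v * n, layer$c_out)
      dw <- crossprod(cache$p, dym)
      db <- colSums(dym)
      dp <- dym %*% t(layer$W)                           # (V*N) x (27*Cin)
      dim(dp) <- c(v, n, 27L, layer$c_in)
      dp <- aperm(dp, c(1, 3, 4, 2))                     # (V,27,C,N)
      dx <- matrix(0, v + 1L, layer$c_in * n)
      for (j in 1:27) {
        tgt <- layer$nbr[, j]
        ok <- tgt <= v
        if (any(ok)) {
          src <- dp[, j, , , drop = FALSE]
          dim(src) <- c(v, layer$c_in * n)
          rows <- tgt[ok]
          dx[rows, ] <- dx[rows, , drop = FALSE] + src[ok, , drop = FALSE]
        }
      }
      list(dx = dx[seq_len(v), , drop = FALSE],
           grads = list(W = dw, b = db))
    },
    bn3d = {
      if (isTRUE(cache$training)) {
        chmap <- cache$chmap
        m <- cache$m
        dbeta <- as.numeric(rowsum(colSums(dy), chmap))
        dgamma <- as.numeric(rowsum(colSums(dy * cache$xhat), chmap))
        a <- (layer$gamma * cache$scale)[chmap]
        dx <- bycol(a, nrow(dy), ncol(dy)) *
          (dy - bycol(dbeta[chmap] / m, nrow(dy), ncol(dy)) -
             cache$xhat * bycol(dgamma[chmap] / m, nrow(dy), ncol(dy)))
        list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
      } else {
        a <- (layer$gamma * cache$scale)[cache$chmap]
        list(dx = dy * bycol(a, nrow(dy), ncol(dy)), grads = NULL)
      }
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    pool = {
      v <- prod(layer$shape_in)
      vp <- nrow(cache$besto)
      dx <- matrix(0, v, ncol(dy))
      for (o in 1:8) {
        w <- which(cache$besto == o)
        if (length(w)) {
          r <- ((w - 1L) %% vp) + 1L
          cc <- ((w - 1L) %/% vp) + 1L
          dx[cbind(layer$idx[r, o], cc)] <- dy[w]
        }
      }
      list(dx = dx, grads = NULL)
    },
    flatten = {
      v <- prod(layer$shape)
      dim(dy) <- c(n, v, layer$c)
      dx <- aperm(dy, c(2, 3, 1))
      dim(dx) <- c(v, layer$c * n)
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = dy %*% t(layer$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    bn1d = {
      if (isTRUE(cache$training)) {
        m <- cache$m
        dbeta <- colSums(dy)
        dgamma <- colSums(dy * cache$xhat)
        a <- layer$gamma * cache$scale
        dx <- bycol(a, m, ncol(dy)) *
          (dy - bycol(dbeta / m, m, ncol(dy)) -
             cache$xhat * bycol(dgamma / m, m, ncol(dy)))
        list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
      } else {
        a <- layer$gamma * cache$scale
        list(dx = dy * bycol(a, nrow(dy), ncol(dy)), grads = NULL)
      }
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    stopf("unknown layer kind '%s'", layer$kind)
  )
}

# Run a whole path; returns output, per-layer caches and (BN-)updated layers.
path_forward <- function(layers, x, n, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- layer_forward(layers[[i]], x, n, training)
    x <- res$y
    caches[[i]] <- res$cache
    layers[[i]] <- res$layer
  }
  list(y = x, caches = caches, layers = layers)
}

# Backward through a path. stop_before: index at which to stop and return
# the incoming gradient (used by Grad-CAM to read d(output)/d(activation)).
path_backward <- function(layers, caches, dy, n, stop_before = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i <= stop_before) break
    res <- layer_backward(layers[[i]], dy, caches[[i]], n)
    dy <- res$dx
    grads[i] <- list(res$grads)     # [[<- would drop NULLs and shift the list
  }
  list(dx = dy, grads = grads)
}
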