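# Compact 1D neural-network engine in base R.  Activations travel as 3D
# arrays (batch, length, channels) through convolutional layers and as
# matrices (batch, features) after flatten/GAP.  Convolutions are computed
# as im2col crops times a BLAS matrix product; every layer implements an
# exact backward pass so the two stress architectures can be trained with
# Adam on cross-entropy.

add_rowvec <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

layer_conv1d <- function(kernel, c_in, c_out, pad = 0L) {
  list(type = "conv1d", kernel = as.integer(kernel), c_in = as.integer(c_in),
       c_out = as.integer(c_out), pad = as.integer(pad),
       params = list(
         W = matrix(stats::rnorm(kernel * c_in * c_out, sd = sqrt(2 / (kernel * c_in))),
                    kernel * c_in, c_out),
         b = numeric(c_out)))
}

layer_maxpool <- function(pool) list(type = "maxpool", pool = as.integer(pool), params = list())
layer_lrelu <- function(alpha = 0.01) list(type = "lrelu", alpha = alpha, params = list())
layer_dropout <- function(rate) list(type = "dropout", rate = rate, params = list())
layer_flatten <- function() list(type = "flatten", params = list())
layer_gap <- function() list(type = "gap", params = list())

layer_batchnorm <- function(c_out, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", c_out = as.integer(c_out), momentum = momentum, eps = eps,
       params = list(gamma = rep(1, c_out), beta = numeric(c_out)),
       state = list(running_mean = numeric(c_out), running_var = rep(1, c_out)))
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = as.integer(n_in), n_out = as.integer(n_out),
       params = list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
                     b = numeric(n_out)))
}

im2col <- function(Xp, K, c_in) {
  d <- dim(Xp); B <- d[1]; Lp <- d[2]
  L_out <- Lp - K + 1L
  M <- matrix(0, B * L_out, K * c_in)
  for (k in seq_len(K))
    M[, (seq_len(c_in) - 1L) * K + k] <-
      matrix(Xp[, k:(k + L_out - 1L), , drop = FALSE], B * L_out, c_in)
  M
}

forward_layer <- function(layer, x, training) {
  switch(layer$type,
    conv1d = {
      d <- dim(x); B <- d[1]; L <- d[2]
      if (layer$pad > 0) {
        Xp <- array(0, c(B, L + 2L * layer$pad, layer$c_in))
        Xp[, layer$pad + seq_len(L), ] <- x
      } else Xp <- x
      M <- im2col(Xp, layer$kernel, layer$c_in)
      Z <- add_rowvec(M %*% layer$params$W, layer$params$b)
      L_out <- dim(Xp)[2] - layer$kernel + 1L
      list(out = array(Z, c(B, L_out, layer$c_out)),
           cache = list(M = M, B = B, L = L, L_out = L_out))
    },
    maxpool = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]; p <- layer$pool
      L_out <- L %/% p
      arr <- x[, seq_len(p * L_out), , drop = FALSE]
      dim(arr) <- c(B, p, L_out, C)
      best <- arr[, 1, , , drop = FALSE]; dim(best) <- c(B, L_out, C)
      besti <- array(1L, c(B, L_out, C))
      if (p > 1) for (i in 2:p) {
        cur <- arr[, i, , , drop = FALSE]; dim(cur) <- c(B, L_out, C)
        upd <- cur > best
        best[upd] <- cur[upd]; besti[upd] <- i
      }
      list(out = best, cache = list(besti = besti, B = B, L = L, C = C, L_out = L_out))
    },
    batchnorm = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]; N <- B * L
      Xm <- matrix(x, N, C)
      if (training) {
        mu <- colMeans(Xm)
        v <- colMeans(Xm * Xm) - mu * mu
        layer$state$running_mean <- (1 - layer$momentum) * layer$state$running_mean +
          layer$momentum * mu
        layer$state$running_var <- (1 - layer$momentum) * layer$state$running_var +
          layer$momentum * v
      } else {
        mu <- layer$state$running_mean
        v <- layer$state$running_var
      }
      ivar <- 1 / sqrt(v + layer$eps)
      xhat <- add_rowvec(Xm, -mu)
      xhat <- xhat * matrix(ivar, N, C, byrow = TRUE)
      out <- add_rowvec(xhat * matrix(layer$params$gamma, N, C, byrow = TRUE),
                        layer$params$beta)
      dim(out) <- c(B, L, C)
      list(out = out, cache = list(xhat = xhat, ivar = ivar, B = B, L = L, C = C),
           layer = layer)   # state may have been updated
    },
    lrelu = {
      neg <- x < 0
      x[neg] <- x[neg] * layer$alpha
      list(out = x, cache = list(neg = neg))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        list(out = x * array(mask, dim(x) %||% length(x)), cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(d = d))
    },
    gap = {
      d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
      out <- matrix(0, B, C)
      for (l in seq_len(L)) out <- out + matrix(x[, l, , drop = FALSE], B, C)
      list(out = out / L, cache = list(d = d))
    },
    dense = {
      list(out = add_rowvec(x %*% layer$params$W, layer$params$b), cache = list(x = x))
    },
    stop("unknown layer type ", layer$type)
  )
}

backward_layer <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    conv1d = {
      dZ <- matrix(dout, cache$B * cache$L_out, layer$c_out)
      grads <- list(W = crossprod(cache$M, dZ), b = colSums(dZ))
      dx <- NULL
      if (need_dx) {
        dM <- dZ %*% t(layer$params$W)
        Lp <- cache$L + 2L * layer$pad
        dXp <- array(0, c(cache$B, Lp, layer$c_in))
        for (k in seq_len(layer$kernel)) {
          idx <- k:(k + cache$L_out - 1L)
          dXp[, idx, ] <- dXp[, idx, , drop = FALSE] +
            array(dM[, (seq_len(layer$c_in) - 1L) * layer$kernel + k],
                  c(cache$B, cache$L_out, layer$c_in))
        }
        dx <- if (layer$pad > 0)
          dXp[, layer$pad + seq_len(cache$L), , drop = FALSE] else dXp
      }
      list(dx = dx, grads = grads)
    },
    maxpool = {
      B <- cache$B; L <- cache$L; C <- cache$C; L_out <- cache$L_out; p <- layer$pool
      dx <- array(0, c(B, L, C))
      bvec <- rep(seq_len(B), times = L_out * C)
      jvec <- rep(rep(seq_len(L_out), each = B), times = C)
      cvec <- rep(seq_len(C), each = B * L_out)
      l <- (jvec - 1L) * p + as.vector(cache$besti)
      dx[bvec + (l - 1L) * B + (cvec - 1L) * (B * L)] <- as.vector(dout)
      list(dx = dx, grads = list())
    },
    batchnorm = {
      B <- cache$B; L <- cache$L; C <- cache$C; N <- B * L
      dY <- matrix(dout, N, C)
      dgamma <- colSums(dY * cache$xhat)
      dbeta <- colSums(dY)
      dxhat <- dY * matrix(layer$params$gamma, N, C, byrow = TRUE)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dX <- (dxhat * N - matrix(s1, N, C, byrow = TRUE) -
               cache$xhat * matrix(s2, N, C, byrow = TRUE)) *
        matrix(cache$ivar / N, N, C, byrow = TRUE)
      dim(dX) <- c(B, L, C)
      list(dx = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      dout[cache$neg] <- dout[cache$neg] * layer$alpha
      list(dx = dout, grads = list())
    },
    dropout = {
      if (!is.null(cache$mask))
        dout <- dout * array(cache$mask, dim(dout) %||% length(dout))
      list(dx = dout, grads = list())
    },
    flatten = {
      dim(dout) <- cache$d
      list(dx = dout, grads = list())
    },
    gap = {
      d <- cache$d
      dx <- array(0, d)
      g <- dout / d[2]
      for (l in seq_len(d[2])) dx[, l, ] <- g
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = if (need_dx) dout %*% t(layer$params$W) else NULL,
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    }
  )
}

# Forward through all layers; returns logits and per-layer caches.  The
# batch-norm layers update running statistics in training mode, so the
# (possibly modified) layers are returned too.
nn_forward <- function(layers, X, training = FALSE) {
  B <- nrow(X)
  x <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- forward_layer(layers[[i]], x, training)
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(logits = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dout <- dlogits
  for (i in rev(seq_along(layers))) {
    r <- backward_layer(layers[[i]], caches[[i]], dout, need_dx = (i > 1))
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  grads
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and its gradient w.r.t. logits for integer labels.
xent_loss <- function(logits, y_int, n_classes) {
  B <- nrow(logits)
  P <- softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), y_int)] + eps))
  Y <- matrix(0, B, n_classes)
  Y[cbind(seq_len(B), y_int)] <- 1
  list(loss = loss, dlogits = (P - Y) / B)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) lapply(ly$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(layers = layers, opt = opt)
}
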