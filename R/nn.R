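# Minimal convolutional network engine backing the virtual-labelling models.
#
# Activations are C x (H*W*N) matrices (pixels column-major per sample,
# samples consecutive); convolutions are im2col + BLAS matmul, transposed
# convolutions the adjoint (col2im). Everything is deterministic given the
# R RNG state, so seeded training runs reproduce exactly on one machine.

.act_geom <- function(a, H, W, N) list(a = a, H = H, W = W, N = N)

.conv_out_dim <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# weight init: N(0, 0.02) conv kernels (pix2pix convention), zero biases
.init_conv <- function(c_in, c_out, k) {
  list(W = matrix(stats::rnorm(c_out * c_in * k * k, 0, 0.02), nrow = c_out),
       b = numeric(c_out))
}
.init_convt <- function(c_in, c_out, k) {
  list(W = matrix(stats::rnorm(c_in * c_out * k * k, 0, 0.02), nrow = c_in),
       b = numeric(c_out))
}
.init_bn <- function(c) {
  list(gamma = stats::rnorm(c, 1, 0.02), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

## ---- forward primitives -------------------------------------------------

.conv_fwd <- function(p, x, k = 4L, stride = 2L, pad = 1L) {
  cols <- .im2col_cpp(x$a, x$H, x$W, x$N, k, stride, pad)
  out <- p$W %*% cols + p$b
  Ho <- .conv_out_dim(x$H, k, stride, pad)
  Wo <- .conv_out_dim(x$W, k, stride, pad)
  list(out = .act_geom(out, Ho, Wo, x$N), cols = cols)
}

.conv_bwd <- function(p, dout, cols, x, k = 4L, stride = 2L, pad = 1L) {
  dW <- dout %*% t(cols)
  db <- rowSums(dout)
  dx <- .col2im_cpp(t(p$W) %*% dout, x$H, x$W, nrow(x$a), x$N, k, stride, pad)
  list(dx = dx, dW = dW, db = db)
}

# transposed conv: geometry (H,W) -> (H*stride, W*stride) for k=4,s=2,p=1
.convt_fwd <- function(p, x, k = 4L, stride = 2L, pad = 1L) {
  Ho <- (x$H - 1L) * stride - 2L * pad + k
  Wo <- (x$W - 1L) * stride - 2L * pad + k
  c_out <- length(p$b)
  out <- .col2im_cpp(t(p$W) %*% x$a, Ho, Wo, c_out, x$N, k, stride, pad)
  out <- out + p$b
  list(out = .act_geom(out, Ho, Wo, x$N))
}

.convt_bwd <- function(p, dout, x, k = 4L, stride = 2L, pad = 1L) {
  # dout lives on the large grid; its im2col re-creates the small geometry
  g_big <- dout$a
  cols_g <- .im2col_cpp(g_big, dout$H, dout$W, dout$N, k, stride, pad)
  dW <- x$a %*% t(cols_g)
  # bias gradient: sum of dout per output channel
  db <- rowSums(g_big)
  dx <- p$W %*% cols_g
  list(dx = dx, dW = dW, db = db)
}

.bn_fwd <- function(p, a, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- rowMeans(a)
    ac <- a - mu
    v <- rowMeans(ac * ac)
    inv <- 1 / sqrt(v + eps)
    xhat <- ac * inv
    out <- p$gamma * xhat + p$beta
    m <- ncol(a)
    vu <- if (m > 1) v * m / (m - 1) else v
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * vu
    list(out = out, cache = list(xhat = xhat, inv = inv), p = p)
  } else {
    inv <- 1 / sqrt(p$rvar + eps)
    list(out = p$gamma * (a - p$rmean) * inv + p$beta,
         cache = list(inv = inv, eval = TRUE), p = p)
  }
}

.bn_bwd <- function(p, dout, cache) {
  if (isTRUE(cache$eval)) {
    # inference mode: running statistics are constants
    return(list(dx = p$gamma * cache$inv * dout, dgamma = NULL, dbeta = NULL))
  }
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  gi <- p$gamma * cache$inv
  dx <- gi * (dout - rowMeans(dout) - xhat * rowMeans(dout * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.lrelu_fwd <- function(a, slope = 0.2) {
  neg <- a < 0
  a[neg] <- a[neg] * slope
  list(out = a, neg = neg)
}
.lrelu_bwd <- function(dout, neg, slope = 0.2) {
  dout[neg] <- dout[neg] * slope
  dout
}

.dropout_fwd <- function(a, p_drop, training) {
  if (!training || p_drop <= 0) return(list(out = a, mask = NULL))
  mask <- (stats::runif(length(a)) >= p_drop) / (1 - p_drop)
  dim(mask) <- dim(a)
  list(out = a * mask, mask = mask)
}

## ---- U-Net --------------------------------------------------------------

.unet_widths <- function(base, depth, cap = 8L) {
  pmin(base * 2L^(seq_len(depth) - 1L), base * cap)
}

.unet_init <- function(c_in, base, depth, c_out = 1L) {
  w <- .unet_widths(base, depth)
  enc <- vector("list", depth)
  prev <- c_in
  for (i in seq_len(depth)) {
    enc[[i]] <- list(conv = .init_conv(prev, w[i], 4L),
                     bn = if (i > 1L) .init_bn(w[i]) else NULL)
    prev <- w[i]
  }
  dec <- vector("list", depth)
  for (j in seq_len(depth)) {
    in_ch <- if (j == 1L) w[depth] else dec[[j - 1L]]$out_ch + w[depth - j + 1L]
    out_ch <- if (j < depth) w[depth - j] else c_out
    dec[[j]] <- list(convt = .init_convt(in_ch, out_ch, 4L),
                     bn = if (j < depth) .init_bn(out_ch) else NULL,
                     dropout = (j <= 3L && depth > 3L),
                     out_ch = out_ch)
  }
  list(enc = enc, dec = dec, depth = depth, widths = w, c_in = c_in, c_out = c_out)
}

# forward pass; training=TRUE keeps caches for backprop and updates BN
# running statistics (returned in $net)
.unet_fwd <- function(net, x, training = FALSE) {
  depth <- net$depth
  skips <- vector("list", depth)
  caches <- list(enc = vector("list", depth), dec = vector("list", depth))
  cur <- x
  for (i in seq_len(depth)) {
    blk <- net$enc[[i]]
    cv <- .conv_fwd(blk$conv, cur)
    lr <- .lrelu_fwd(cv$out$a)
    a <- lr$out
    bn_cache <- NULL
    if (!is.null(blk$bn)) {
      bf <- .bn_fwd(blk$bn, a, training)
      a <- bf$out; bn_cache <- bf$cache
      if (training) net$enc[[i]]$bn <- bf$p
    }
    caches$enc[[i]] <- list(cols = cv$cols, x_in = cur, neg = lr$neg, bn = bn_cache)
    cur <- .act_geom(a, cv$out$H, cv$out$W, cv$out$N)
    skips[[i]] <- cur
  }
  for (j in seq_len(depth)) {
    blk <- net$dec[[j]]
    xin <- if (j == 1L) skips[[depth]] else {
      sk <- skips[[depth - j + 1L]]
      .act_geom(rbind(cur$a, sk$a), cur$H, cur$W, cur$N)
    }
    tv <- .convt_fwd(blk$convt, xin)
    a <- tv$out$a
    cache <- list(x_in = xin, split = if (j > 1L) nrow(cur$a) else NA_integer_)
    if (j < depth) {
      # order: activation (ReLU) then BN, then dropout
      neg <- a < 0
      a[neg] <- 0
      cache$neg <- neg
      if (!is.null(blk$bn)) {
        bf <- .bn_fwd(blk$bn, a, training)
        a <- bf$out; cache$bn <- bf$cache
        if (training) net$dec[[j]]$bn <- bf$p
      }
      if (blk$dropout) {
        dr <- .dropout_fwd(a, 0.5, training)
        a <- dr$out; cache$mask <- dr$mask
      }
    } else {
      a <- tanh(a)
      cache$tanh_out <- a
    }
    caches$dec[[j]] <- cache
    cur <- .act_geom(a, tv$out$H, tv$out$W, tv$out$N)
  }
  list(out = cur, caches = caches, net = net)
}

# returns gradients shaped like the parameter tree, plus d(input)
.unet_bwd <- function(net, fwd, dout_a) {
  depth <- net$depth
  caches <- fwd$caches
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  cur <- dout_a
  dskips <- vector("list", depth)
  for (j in rev(seq_len(depth))) {
    blk <- net$dec[[j]]
    cache <- caches$dec[[j]]
    if (j == depth) {
      cur <- cur * (1 - cache$tanh_out^2)
    } else {
      if (!is.null(cache$mask)) cur <- cur * cache$mask
      if (!is.null(blk$bn)) {
        bb <- .bn_bwd(blk$bn, cur, cache$bn)
        grads$dec[[j]]$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
        cur <- bb$dx
      }
      cur[cache$neg] <- 0
    }
    xin <- cache$x_in
    Hout <- xin$H * 2L; Wout <- xin$W * 2L
    dg <- .act_geom(cur, Hout, Wout, xin$N)
    tb <- .convt_bwd(blk$convt, dg, xin)
    grads$dec[[j]]$convt <- list(W = tb$dW, b = tb$db)
    if (j > 1L) {
      sp <- cache$split
      cur <- tb$dx[seq_len(sp), , drop = FALSE]
      skip_idx <- depth - j + 1L
      dsk <- tb$dx[(sp + 1L):nrow(tb$dx), , drop = FALSE]
      dskips[[skip_idx]] <- if (is.null(dskips[[skip_idx]])) dsk else dskips[[skip_idx]] + dsk
    } else {
      dskips[[depth]] <- if (is.null(dskips[[depth]])) tb$dx else dskips[[depth]] + tb$dx
      cur <- NULL
    }
  }
  cur <- dskips[[depth]]
  for (i in rev(seq_len(depth))) {
    blk <- net$enc[[i]]
    cache <- caches$enc[[i]]
    if (i < depth && !is.null(dskips[[i]])) cur <- cur + dskips[[i]]
    if (!is.null(blk$bn)) {
      bb <- .bn_bwd(blk$bn, cur, cache$bn)
      grads$enc[[i]]$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cur <- bb$dx
    }
    cur <- .lrelu_bwd(cur, cache$neg)
    cb <- .conv_bwd(blk$conv, cur, cache$cols, cache$x_in)
    grads$enc[[i]]$conv <- list(W = cb$dW, b = cb$db)
    cur <- cb$dx
  }
  list(grads = grads, dx = cur)
}

## ---- PatchGAN discriminator --------------------------------------------

.disc_init <- function(c_in, base) {
  w <- pmin(base * 2L^(0:3), base * 8L)
  layers <- list()
  prev <- c_in
  for (i in 1:4) {
    layers[[i]] <- list(conv = .init_conv(prev, w[i], 4L), stride = 2L,
                        bn = if (i > 1L) .init_bn(w[i]) else NULL)
    prev <- w[i]
  }
  layers[[5]] <- list(conv = .init_conv(prev, w[4], 4L), stride = 1L, bn = .init_bn(w[4]))
  layers[[6]] <- list(conv = .init_conv(w[4], 1L, 4L), stride = 1L, bn = NULL)
  list(layers = layers, c_in = c_in)
}

.disc_fwd <- function(disc, x, training = FALSE) {
  caches <- vector("list", length(disc$layers))
  cur <- x
  for (i in seq_along(disc$layers)) {
    blk <- disc$layers[[i]]
    cv <- .conv_fwd(blk$conv, cur, stride = blk$stride)
    a <- cv$out$a
    cache <- list(cols = cv$cols, x_in = cur, stride = blk$stride)
    if (i < length(disc$layers)) {
      lr <- .lrelu_fwd(a)
      a <- lr$out; cache$neg <- lr$neg
      if (!is.null(blk$bn)) {
        bf <- .bn_fwd(blk$bn, a, training)
        a <- bf$out; cache$bn <- bf$cache
        if (training) disc$layers[[i]]$bn <- bf$p
      }
    }
    caches[[i]] <- cache
    cur <- .act_geom(a, cv$out$H, cv$out$W, cv$out$N)
  }
  list(out = cur, caches = caches, disc = disc)
}

.disc_bwd <- function(disc, fwd, dout_a) {
  n <- length(disc$layers)
  grads <- vector("list", n)
  cur <- dout_a
  for (i in rev(seq_len(n))) {
    blk <- disc$layers[[i]]
    cache <- fwd$caches[[i]]
    if (i < n) {
      if (!is.null(blk$bn)) {
        bb <- .bn_bwd(blk$bn, cur, cache$bn)
        grads[[i]]$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
        cur <- bb$dx
      }
      cur <- .lrelu_bwd(cur, cache$neg)
    }
    cb <- .conv_bwd(blk$conv, cur, cache$cols, cache$x_in, stride = cache$stride)
    grads[[i]]$conv <- list(W = cb$dW, b = cb$db)
    cur <- cb$dx
  }
  list(grads = grads, dx = cur)
}

## ---- Adam ---------------------------------------------------------------

# recursive walk over the parameter tree; only leaves named W/b/gamma/beta
# are trainable (rmean/rvar are batch-norm running statistics)
.trainable_leaves <- c("W", "b", "gamma", "beta")

.adam_init <- function(params) {
  walk <- function(p) {
    if (!is.list(p)) return(NULL)
    out <- vector("list", length(p))
    names(out) <- names(p)
    nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      if (nms[i] %in% .trainable_leaves && is.numeric(p[[i]])) {
        out[[i]] <- list(m = p[[i]] * 0, v = p[[i]] * 0)
      } else if (is.list(p[[i]])) {
        out[[i]] <- walk(p[[i]])
      }
    }
    out
  }
  walk(params)
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    nms <- if (is.null(names(p))) rep("", length(p)) else names(p)
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      gi <- if (!is.null(names(g)) && nms[i] != "") g[[nms[i]]]
            else if (i <= length(g)) g[[i]] else NULL
      si <- if (!is.null(names(s)) && nms[i] != "") s[[nms[i]]]
            else if (i <= length(s)) s[[i]] else NULL
      if (is.null(gi) || is.null(si)) next
      if (nms[i] %in% .trainable_leaves && is.numeric(p[[i]])) {
        sl <- si
        sl$m <- beta1 * sl$m + (1 - beta1) * gi
        sl$v <- beta2 * sl$v + (1 - beta2) * gi * gi
        mhat <- sl$m / (1 - beta1^t)
        vhat <- sl$v / (1 - beta2^t)
        p[[i]] <- p[[i]] - lr * mhat / (sqrt(vhat) + eps)
        s[[i]] <- sl
      } else if (is.list(p[[i]])) {
        r <- walk(p[[i]], gi, si)
        p[[i]] <- r$p; s[[i]] <- r$s
      }
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

# learning rate: constant for epochs_const, then linear decay to zero
#' @keywords internal
.lr_at_epoch <- function(epoch0, lr, epochs_const, epochs_decay) {
  if (epoch0 < epochs_const) return(lr)
  k <- epoch0 - epochs_const
  lr * (1 - k / epochs_decay)
}
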