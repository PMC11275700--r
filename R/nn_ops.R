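# Internal neural-network primitives.
#
# Feature maps are arrays (h, w, channels, batch). Convolution is im2col +
# BLAS matmul with index plans precomputed per input geometry; all backward
# passes are hand-derived and verified against finite differences in the
# test suite.

conv_plan <- function(in_h, in_w, c_in, kh, kw, stride, pad) {
  hp <- in_h + 2 * pad; wp <- in_w + 2 * pad
  out_h <- floor((hp - kh) / stride) + 1
  out_w <- floor((wp - kw) / stride) + 1
  if (out_h < 1 || out_w < 1) {
    stopf("conv geometry collapses: input %dx%d, kernel %d, stride %d, pad %d",
          in_h, in_w, kh, stride, pad)
  }
  k_dim <- kh * kw * c_in
  l_dim <- out_h * out_w
  ky <- rep(seq_len(kh), times = kw * c_in)
  kx <- rep(rep(seq_len(kw), each = kh), times = c_in)
  kc <- rep(seq_len(c_in), each = kh * kw)
  oy <- rep(seq_len(out_h), times = out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  y <- outer(ky, (oy - 1L) * stride, "+")          # K x L
  x <- outer(kx, (ox - 1L) * stride, "+")
  idx <- y + (x - 1L) * hp + (kc - 1L) * (hp * wp)
  iv <- as.vector(idx)
  list(in_h = in_h, in_w = in_w, c_in = c_in, kh = kh, kw = kw,
       stride = stride, pad = pad, hp = hp, wp = wp,
       out_h = out_h, out_w = out_w, k_dim = k_dim, l_dim = l_dim,
       idx = iv, ug = sort(unique(iv)))
}

conv_forward <- function(x, w_mat, bias, plan) {
  b <- dim(x)[4]
  if (plan$pad > 0) {
    xp <- array(0, c(plan$hp, plan$wp, plan$c_in, b))
    xp[plan$pad + seq_len(plan$in_h), plan$pad + seq_len(plan$in_w), , ] <- x
  } else xp <- x
  dim(xp) <- c(plan$hp * plan$wp * plan$c_in, b)
  cols <- xp[plan$idx, , drop = FALSE]             # (K*L) x B
  dim(cols) <- c(plan$k_dim, plan$l_dim * b)
  out <- crossprod(w_mat, cols) + bias             # Cout x (L*B)
  c_out <- length(bias)
  dim(out) <- c(c_out, plan$out_h, plan$out_w, b)
  list(y = aperm(out, c(2, 3, 1, 4)), cols = cols, b = b)
}

conv_backward <- function(dy, w_mat, cache, plan) {
  b <- cache$b
  c_out <- dim(dy)[3]
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(c_out, plan$l_dim * b)
  db <- rowSums(dym)
  dw <- cache$cols %*% t(dym)                      # K x Cout
  dcols <- w_mat %*% dym                           # K x (L*B)
  dim(dcols) <- c(plan$k_dim * plan$l_dim, b)
  acc <- rowsum(dcols, plan$idx)                   # rows: sorted unique idx
  dxp <- matrix(0, plan$hp * plan$wp * plan$c_in, b)
  dxp[plan$ug, ] <- acc
  dim(dxp) <- c(plan$hp, plan$wp, plan$c_in, b)
  dx <- dxp[plan$pad + seq_len(plan$in_h), plan$pad + seq_len(plan$in_w), , ,
            drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       running_mean = rep(0, c_out), running_var = rep(1, c_out))
}

bn_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc * xc)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * va
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
    xc <- sweep(xm, 2, mu)
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, ivar, "*")
  ym <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  dim(ym) <- c(d[1], d[2], d[4], d[3])
  list(y = aperm(ym, c(1, 2, 4, 3)), bn = bn,
       cache = list(xhat = xhat, ivar = ivar, d = d, training = training))
}

bn_backward <- function(dy, bn, cache) {
  d <- cache$d
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  if (cache$training) {
    t1 <- sweep(dym, 2, dbeta / n)
    t2 <- sweep(cache$xhat, 2, dgamma / n, "*")
    dxm <- sweep(t1 - t2, 2, bn$gamma * cache$ivar, "*")
  } else {
    dxm <- sweep(dym, 2, bn$gamma * cache$ivar, "*")
  }
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, mask) dy * mask

pool_plan <- function(h, w, k, stride) {
  out_h <- floor((h - k) / stride) + 1
  out_w <- floor((w - k) / stride) + 1
  if (out_h < 1 || out_w < 1) {
    stopf("pooling geometry collapses: map %dx%d, window %d, stride %d", h, w, k, stride)
  }
  ky <- rep(seq_len(k), times = k)
  kx <- rep(seq_len(k), each = k)
  oy <- rep(seq_len(out_h), times = out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  y <- outer(ky, (oy - 1L) * stride, "+")
  x <- outer(kx, (ox - 1L) * stride, "+")
  list(h = h, w = w, k2 = k * k, out_h = out_h, out_w = out_w,
       l_dim = out_h * out_w, idx = y + (x - 1L) * h)   # k2 x L into h*w plane
}

maxpool_forward <- function(x, plan) {
  d <- dim(x)
  cb <- d[3] * d[4]
  xm <- x; dim(xm) <- c(d[1] * d[2], cb)
  vals <- xm[as.vector(plan$idx), , drop = FALSE]
  dim(vals) <- c(plan$k2, plan$l_dim * cb)
  m <- vals[1, ]
  arg <- rep(1L, length(m))
  for (k in 2:plan$k2) {
    upd <- vals[k, ] > m
    m[upd] <- vals[k, upd]
    arg[upd] <- k
  }
  y <- m
  dim(y) <- c(plan$out_h, plan$out_w, d[3], d[4])
  list(y = y, arg = matrix(arg, plan$l_dim, cb), d = d)
}

maxpool_backward <- function(dy, cache, plan) {
  d <- cache$d
  cb <- d[3] * d[4]
  dym <- dy; dim(dym) <- c(plan$l_dim, cb)
  dxm <- matrix(0, d[1] * d[2], cb)
  idx <- matrix(plan$idx, plan$k2, plan$l_dim)
  for (k in seq_len(plan$k2)) {
    contrib <- dym * (cache$arg == k)
    rows <- idx[k, ]
    dxm[rows, ] <- dxm[rows, ] + contrib
  }
  dim(dxm) <- c(d[1], d[2], d[3], d[4])
  dxm
}

# --- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
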