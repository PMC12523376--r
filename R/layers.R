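# Primitive differentiable layers.
#
# Every forward returns list(out = <fmap or matrix>, cache = <...>); the
# matching backward takes the cache and the upstream gradient and returns the
# input gradient plus gradients for any trainable arrays. All convolutions are
# expressed as (grouped) matrix products on the row-major fmap layout, so the
# heavy lifting is BLAS.

# ---- GELU (exact, erf-based) ----------------------------------------------

gelu_forward <- function(x) {
  Phi <- stats::pnorm(x)
  list(out = x * Phi, cache = list(x = x, Phi = Phi))
}

gelu_backward <- function(cache, dout) {
  x <- cache$x
  dout * (cache$Phi + x * exp(-0.5 * x * x) / sqrt(2 * pi))
}

# ---- convolution -----------------------------------------------------------
# Weight layout: W is a (kh*kw*cin/groups) x cout matrix whose columns are
# grouped by output group; within a column, rows run window-slot-major and
# channel-minor (slot 1 channels, slot 2 channels, ...). b is length cout.

conv_spec <- function(k, stride, cin, cout, groups = 1L, bias = TRUE) {
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop(sprintf("conv channels (%d -> %d) not divisible by groups = %d",
                 cin, cout, groups), call. = FALSE)
  list(k = as.integer(k), stride = as.integer(stride), cin = as.integer(cin),
       cout = as.integer(cout), groups = as.integer(groups), bias = bias)
}

conv_param_count <- function(spec) {
  spec$k * spec$k * spec$cin * spec$cout / spec$groups +
    if (spec$bias) spec$cout else 0L
}

conv_init <- function(spec) {
  fan_in <- spec$k * spec$k * spec$cin / spec$groups
  W <- matrix(stats::rnorm(fan_in * spec$cout, sd = sqrt(2 / fan_in)),
              nrow = fan_in, ncol = spec$cout)
  list(W = W, b = if (spec$bias) numeric(spec$cout) else NULL, spec = spec)
}

conv_forward <- function(fm, par) {
  sp <- par$spec
  if (ncol(fm$x) != sp$cin)
    stop(sprintf("convolution expects %d input channels, got %d",
                 sp$cin, ncol(fm$x)), call. = FALSE)
  g <- sp$groups
  if (sp$k == 1L && sp$stride == 1L) {
    if (g == 1L) {
      Y <- fm$x %*% par$W
    } else {
      Y <- matrix(0, nrow(fm$x), sp$cout)
      cig <- sp$cin %/% g; cog <- sp$cout %/% g
      for (gi in seq_len(g)) {
        ic <- ((gi - 1L) * cig + 1L):(gi * cig)
        oc <- ((gi - 1L) * cog + 1L):(gi * cog)
        Y[, oc] <- fm$x[, ic, drop = FALSE] %*% par$W[, oc, drop = FALSE]
      }
    }
    if (!is.null(par$b)) Y <- sweep(Y, 2L, par$b, "+")
    return(list(out = fmap(Y, fm$n, fm$h, fm$w),
                cache = list(fm = fm, par = par, idx = NULL)))
  }
  if (fm$h %% sp$stride != 0L || fm$w %% sp$stride != 0L)
    stop(sprintf("spatial size %dx%d not divisible by stride %d",
                 fm$h, fm$w, sp$stride), call. = FALSE)
  wi <- window_index(fm$h, fm$w, fm$n, sp$k, sp$k, sp$stride, 0L)
  Xa <- rbind(fm$x, 0)
  cig <- sp$cin %/% g; cog <- sp$cout %/% g
  K <- sp$k * sp$k
  Y <- matrix(0, nrow(wi$idx), sp$cout)
  patches <- vector("list", g)
  for (gi in seq_len(g)) {
    ic <- ((gi - 1L) * cig + 1L):(gi * cig)
    oc <- ((gi - 1L) * cog + 1L):(gi * cog)
    P <- matrix(0, nrow(wi$idx), K * cig)
    for (k in seq_len(K))
      P[, ((k - 1L) * cig + 1L):(k * cig)] <- Xa[wi$idx[, k], ic, drop = FALSE]
    Y[, oc] <- P %*% par$W[, oc, drop = FALSE]
    patches[[gi]] <- P
  }
  if (!is.null(par$b)) Y <- sweep(Y, 2L, par$b, "+")
  list(out = fmap(Y, fm$n, wi$oh, wi$ow),
       cache = list(fm = fm, par = par, idx = wi, patches = patches))
}

conv_backward <- function(cache, dout, need_dx = TRUE) {
  fm <- cache$fm; par <- cache$par; sp <- par$spec
  g <- sp$groups
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  db <- if (!is.null(par$b)) colSums(dout$x) else NULL
  if (is.null(cache$idx)) {                     # 1x1, stride 1
    dX <- if (need_dx) matrix(0, nrow(fm$x), sp$cin) else NULL
    cig <- sp$cin %/% g; cog <- sp$cout %/% g
    for (gi in seq_len(g)) {
      ic <- ((gi - 1L) * cig + 1L):(gi * cig)
      oc <- ((gi - 1L) * cog + 1L):(gi * cog)
      dW[, oc] <- crossprod(fm$x[, ic, drop = FALSE], dout$x[, oc, drop = FALSE])
      if (need_dx)
        dX[, ic] <- dout$x[, oc, drop = FALSE] %*% t(par$W[, oc, drop = FALSE])
    }
    return(list(dx = if (need_dx) fmap(dX, fm$n, fm$h, fm$w) else NULL,
                dW = dW, db = db))
  }
  wi <- cache$idx
  cig <- sp$cin %/% g; cog <- sp$cout %/% g
  K <- sp$k * sp$k
  dX <- if (need_dx) matrix(0, nrow(fm$x) + 1L, sp$cin) else NULL
  for (gi in seq_len(g)) {
    ic <- ((gi - 1L) * cig + 1L):(gi * cig)
    oc <- ((gi - 1L) * cog + 1L):(gi * cog)
    dW[, oc] <- crossprod(cache$patches[[gi]], dout$x[, oc, drop = FALSE])
    if (need_dx) {
      dP <- dout$x[, oc, drop = FALSE] %*% t(par$W[, oc, drop = FALSE])
      for (k in seq_len(K)) {
        # stride >= k here, so each window slot maps output rows injectively
        dX[wi$idx[, k], ic] <- dX[wi$idx[, k], ic, drop = FALSE] +
          dP[, ((k - 1L) * cig + 1L):(k * cig), drop = FALSE]
      }
    }
  }
  list(dx = if (need_dx)
         fmap(dX[-nrow(dX), , drop = FALSE], fm$n, fm$h, fm$w) else NULL,
       dW = dW, db = db)
}

# ---- batch normalization ---------------------------------------------------
# Per-channel affine normalization; training mode uses batch statistics over
# all rows (images x positions), evaluation mode the running estimates.

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       mean = rep(0, channels), var = rep(1, channels),
       channels = as.integer(channels))
}

bn_forward <- function(fm, par, training, eps = 1e-5, momentum = 0.1) {
  X <- fm$x
  if (ncol(X) != par$channels)
    stop(sprintf("batch norm expects %d channels, got %d",
                 par$channels, ncol(X)), call. = FALSE)
  if (training) {
    m <- nrow(X)
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2            # biased, as used in normalization
    va <- pmax(va, 0)
    new_mean <- (1 - momentum) * par$mean + momentum * mu
    unb <- if (m > 1) va * m / (m - 1) else va
    new_var <- (1 - momentum) * par$var + momentum * unb
  } else {
    mu <- par$mean; va <- par$var
    new_mean <- par$mean; new_var <- par$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2L, mu, "-"), 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(out = fmap(Y, fm$n, fm$h, fm$w),
       cache = list(xhat = xhat, invstd = invstd, gamma = par$gamma,
                    training = training, n = fm$n, h = fm$h, w = fm$w),
       run = list(mean = new_mean, var = new_var))
}

bn_backward <- function(cache, dout) {
  dY <- dout$x
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$training) {
    m <- nrow(dY)
    t1 <- sweep(dY, 2L, dbeta / m, "-")
    t2 <- sweep(cache$xhat, 2L, dgamma / m, "*")
    dX <- sweep(t1 - t2, 2L, cache$gamma * cache$invstd, "*")
  } else {
    dX <- sweep(dY, 2L, cache$gamma * cache$invstd, "*")
  }
  list(dx = fmap(dX, cache$n, cache$h, cache$w), dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling ---------------------------------------------------------------
# Average pooling counts zero padding in the fixed divisor k^2; max pooling
# pads with -Inf (padding never wins). Ties in max pooling resolve to the
# first window slot in row-major order.

avgpool_forward <- function(fm, k, stride, pad) {
  wi <- window_index(fm$h, fm$w, fm$n, k, k, stride, pad)
  Xa <- rbind(fm$x, 0)
  S <- Xa[wi$idx[, 1L], , drop = FALSE]
  for (s in 2L:(k * k)) S <- S + Xa[wi$idx[, s], , drop = FALSE]
  list(out = fmap(S / (k * k), fm$n, wi$oh, wi$ow),
       cache = list(wi = wi, k = k, n = fm$n, h = fm$h, w = fm$w,
                    rows_in = nrow(fm$x)))
}

avgpool_backward <- function(cache, dout) {
  k <- cache$k; wi <- cache$wi
  dX <- matrix(0, cache$rows_in + 1L, ncol(dout$x))
  dY <- dout$x / (k * k)
  for (s in seq_len(k * k))
    dX[wi$idx[, s], ] <- dX[wi$idx[, s], , drop = FALSE] + dY
  fmap(dX[-nrow(dX), , drop = FALSE], cache$n, cache$h, cache$w)
}

maxpool_forward <- function(fm, k, stride, pad) {
  wi <- window_index(fm$h, fm$w, fm$n, k, k, stride, pad)
  Xa <- rbind(fm$x, -Inf)
  M <- Xa[wi$idx[, 1L], , drop = FALSE]
  A <- matrix(1L, nrow(M), ncol(M))
  for (s in 2L:(k * k)) {
    G <- Xa[wi$idx[, s], , drop = FALSE]
    upd <- G > M
    M[upd] <- G[upd]
    A[upd] <- s
  }
  list(out = fmap(M, fm$n, wi$oh, wi$ow),
       cache = list(wi = wi, k = k, arg = A, n = fm$n, h = fm$h, w = fm$w,
                    rows_in = nrow(fm$x)))
}

maxpool_backward <- function(cache, dout) {
  wi <- cache$wi; k <- cache$k
  rows_out <- nrow(dout$x); nc <- ncol(dout$x)
  rows_aug <- cache$rows_in + 1L
  dX <- matrix(0, rows_aug, nc)
  for (s in seq_len(k * k)) {
    li <- which(cache$arg == s)
    if (length(li) == 0L) next
    r <- (li - 1L) %% rows_out + 1L
    cc <- (li - 1L) %/% rows_out
    tgt <- wi$idx[r, s] + cc * rows_aug     # unique within a slot
    dX[tgt] <- dX[tgt] + dout$x[li]
  }
  fmap(dX[-rows_aug, , drop = FALSE], cache$n, cache$h, cache$w)
}

# ---- global average pooling ------------------------------------------------

gap_forward <- function(fm) {
  grp <- rep(seq_len(fm$n), each = fm$h * fm$w)
  out <- rowsum(fm$x, grp, reorder = FALSE) / (fm$h * fm$w)
  list(out = out, cache = list(n = fm$n, h = fm$h, w = fm$w))
}

gap_backward <- function(cache, dout) {
  dX <- dout[rep(seq_len(cache$n), each = cache$h * cache$w), , drop = FALSE] /
    (cache$h * cache$w)
  fmap(dX, cache$n, cache$h, cache$w)
}

# ---- fully connected + softmax --------------------------------------------

fc_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

fc_forward <- function(X, par) {
  list(out = sweep(X %*% par$W, 2L, par$b, "+"), cache = list(X = X, par = par))
}

fc_backward <- function(cache, dout) {
  list(dx = dout %*% t(cache$par$W), dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
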