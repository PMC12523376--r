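# Slow, loop-based reference implementations used as independent oracles.
# They work directly on h x w x c arrays with explicit loops and share no
# code with the package internals.

oracle_conv2d <- function(a, W, b, k, stride, groups = 1L) {
  H <- dim(a)[1]; Wd <- dim(a)[2]; cin <- dim(a)[3]
  cout <- ncol(W)
  cig <- cin / groups; cog <- cout / groups
  oh <- (H - k) / stride + 1; ow <- (Wd - k) / stride + 1
  out <- array(0, c(oh, ow, cout))
  for (oc in seq_len(cout)) {
    gi <- ceiling(oc / cog)
    ic <- ((gi - 1) * cig + 1):(gi * cig)
    for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
      acc <- if (is.null(b)) 0 else b[oc]
      for (dh in seq_len(k)) for (dw in seq_len(k)) {
        slot <- (dh - 1) * k + dw
        for (cl in seq_len(cig)) {
          acc <- acc + a[(oi - 1) * stride + dh, (oj - 1) * stride + dw,
                         ic[cl]] * W[(slot - 1) * cig + cl, oc]
        }
      }
      out[oi, oj, oc] <- acc
    }
  }
  out
}

# average pooling counts zero padding in the fixed k^2 divisor; max pooling
# ignores padded positions entirely
oracle_pool <- function(a, k, stride, pad, type = c("avg", "max")) {
  type <- match.arg(type)
  H <- dim(a)[1]; Wd <- dim(a)[2]; C <- dim(a)[3]
  oh <- (H + 2 * pad - k) / stride + 1; ow <- (Wd + 2 * pad - k) / stride + 1
  out <- array(0, c(oh, ow, C))
  for (ci in seq_len(C)) for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
    vals <- c()
    for (dh in seq_len(k)) for (dw in seq_len(k)) {
      sh <- (oi - 1) * stride - pad + dh
      sw <- (oj - 1) * stride - pad + dw
      if (sh >= 1 && sh <= H && sw >= 1 && sw <= Wd)
        vals <- c(vals, a[sh, sw, ci])
    }
    out[oi, oj, ci] <- if (type == "avg") sum(vals) / (k * k) else max(vals)
  }
  out
}

oracle_bn_eval <- function(a, gamma, beta, mu, va, eps = 1e-5) {
  out <- a
  for (ci in seq_len(dim(a)[3]))
    out[, , ci] <- (a[, , ci] - mu[ci]) / sqrt(va[ci] + eps) * gamma[ci] +
      beta[ci]
  out
}

oracle_gelu <- function(x) x * pnorm(x)

oracle_stem <- function(a, par, eps = 1e-5) {
  p <- oracle_conv2d(a, par$patch$W, par$patch$b, k = 4, stride = 4)
  bnp <- par$bn
  B <- oracle_bn_eval(p, bnp$gamma, bnp$beta, bnp$mean, bnp$var, eps)
  e <- oracle_conv2d(B, par$expand$W, par$expand$b, k = 1, stride = 1,
                     groups = par$expand$spec$groups)
  pr <- oracle_conv2d(oracle_gelu(e), par$project$W, par$project$b, 1, 1)
  pr + B
}

oracle_attention <- function(a, par, eps = 1e-5) {
  bnp <- par$bn
  B <- oracle_bn_eval(a, bnp$gamma, bnp$beta, bnp$mean, bnp$var, eps)
  av <- oracle_pool(B, 3, 1, 1, "avg")
  mx <- oracle_pool(B, 3, 1, 1, "max")
  gate <- 1 / (1 + exp(-(av * mx)))
  f <- dim(a)[3]
  cat2 <- array(0, c(dim(a)[1], dim(a)[2], 2 * f))
  cat2[, , 1:f] <- gate
  cat2[, , (f + 1):(2 * f)] <- B
  z <- oracle_pool(cat2, 3, 1, 1, "avg")
  pr <- oracle_conv2d(oracle_gelu(z), par$project$W, par$project$b, 1, 1)
  pr + B
}

oracle_bottleneck <- function(a, par, eps = 1e-5) {
  bnp <- par$bn
  B <- oracle_bn_eval(a, bnp$gamma, bnp$beta, bnp$mean, bnp$var, eps)
  e <- oracle_conv2d(B, par$expand$W, par$expand$b, 1, 1,
                     groups = par$expand$spec$groups)
  pr <- oracle_conv2d(oracle_gelu(e), par$project$W, par$project$b, 1, 1)
  pr + a
}

oracle_downsample <- function(a, par) {
  f <- dim(a)[3]
  av <- oracle_pool(a, 2, 2, 0, "avg")
  mx <- oracle_pool(a, 2, 2, 0, "max")
  cv <- oracle_conv2d(a, par$conv$W, par$conv$b, 2, 2,
                      groups = par$conv$spec$groups)
  S <- array(0, dim(cv))
  S[, , 1:f] <- av
  S[, , (f + 1):(2 * f)] <- mx
  oracle_gelu(S + cv)
}

oracle_head <- function(a, par) {
  C <- dim(a)[3]
  g <- numeric(C)
  for (ci in seq_len(C)) g[ci] <- mean(a[, , ci])
  z <- drop(g %*% par$fc$W) + par$fc$b
  e <- exp(z - max(z))
  e / sum(e)
}

# independent scalar-arithmetic metric formulas for a binary confusion
# matrix given as TP/FN/FP/TN of the support (first) class, percent scale
ref_metrics_2x2 <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  prec1 <- if (tp + fp > 0) tp / (tp + fp) else 0
  prec2 <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec1 <- if (tp + fn > 0) tp / (tp + fn) else 0
  rec2 <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1_1 <- if (prec1 + rec1 > 0) 2 * prec1 * rec1 / (prec1 + rec1) else 0
  f1_2 <- if (prec2 + rec2 > 0) 2 * prec2 * rec2 / (prec2 + rec2) else 0
  list(accuracy = 100 * (tp + tn) / n,
       precision = 100 * c(prec1, prec2),
       recall = 100 * c(rec1, rec2),
       f1 = 100 * c(f1_1, f1_2),
       macro_precision = 100 * (prec1 + prec2) / 2,
       macro_recall = 100 * (rec1 + rec2) / 2,
       macro_f1 = 100 * (f1_1 + f1_2) / 2,
       sensitivity = 100 * rec1, specificity = 100 * rec2,
       g_mean = 100 * sqrt(rec1 * rec2),
       balanced_accuracy = 100 * (rec1 + rec2) / 2)
}

# randomize the batch-norm buffers/affine of a freshly built block so that
# evaluation-mode forward exercises non-trivial normalization
randomize_bn <- function(par) {
  for (k in names(par)) {
    if (!is.null(par[[k]]$gamma)) {
      ch <- par[[k]]$channels
      par[[k]]$gamma <- runif(ch, 0.5, 1.5)
      par[[k]]$beta <- rnorm(ch, 0, 0.2)
      par[[k]]$mean <- rnorm(ch, 0, 0.3)
      par[[k]]$var <- runif(ch, 0.5, 2)
    } else if (is.list(par[[k]]) && is.null(par[[k]]$W)) {
      par[[k]] <- randomize_bn(par[[k]])
    }
  }
  par
}
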