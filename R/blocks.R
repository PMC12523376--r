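# The four TurkerNeXtV2 operators and the classification head.
#
# Each block has an init_* constructor building its weight container, a
# *_forward returning list(out, cache, run) where `run` carries updated
# batch-norm running statistics, and a *_backward returning the input
# gradient and a gradient list parallel to the weight container.
#
# Weight containers are plain named lists so a checkpoint is just the nested
# list; batch-norm running statistics live beside the trainable arrays but
# are not counted as trainable.

.default_groups <- function() list(stem = 4L, expansion = 4L, downsample = 2L)

# ---- patchify stem ---------------------------------------------------------
# P = Conv 4x4 stride 4 (3 -> F); B = BN(P) (single shared instance);
# out = Conv1x1_F( GELU( GConv1x1_{4F} (B) ) ) + B. One GELU total.

init_stem <- function(f1, in_channels = 3L, groups = 4L) {
  list(patch = conv_init(conv_spec(4L, 4L, in_channels, f1)),
       bn = bn_init(f1),
       expand = conv_init(conv_spec(1L, 1L, f1, 4L * f1, groups = groups)),
       project = conv_init(conv_spec(1L, 1L, 4L * f1, f1)))
}

#' Patchify stem
#'
#' Embeds the input image into a coarse grid: an aggressive 4x4 stride-4
#' convolution ("patchify"), one shared batch normalization, and a light
#' grouped inverted bottleneck (expand to 4F with a grouped 1x1 convolution,
#' one GELU, project back to F) added residually to the normalized patch
#' embedding. For a 224x224x3 input and F = 96 the output is 56x56x96.
#'
#' @param fm input [fmap] (channels must match the stem's patchify spec;
#'   spatial dimensions divisible by 4).
#' @param par stem weights as built by [build_network()] (element `stem`).
#' @param training logical; batch statistics vs. running statistics.
#' @param eps,momentum batch-norm constants.
#' @return list with `out` (the [fmap]), `cache` (for the backward pass) and
#'   `run` (updated running statistics).
#' @export
patchify_stem <- function(fm, par, training = FALSE, eps = 1e-5,
                          momentum = 0.1) {
  if (fm$h %% 4L != 0L || fm$w %% 4L != 0L)
    stop(sprintf("stem needs spatial size divisible by 4, got %dx%d",
                 fm$h, fm$w), call. = FALSE)
  p <- conv_forward(fm, par$patch)
  b <- bn_forward(p$out, par$bn, training, eps, momentum)
  e <- conv_forward(b$out, par$expand)
  g <- gelu_forward(e$out$x)
  ge <- fmap(g$out, e$out$n, e$out$h, e$out$w)
  pr <- conv_forward(ge, par$project)
  out <- fmap(pr$out$x + b$out$x, pr$out$n, pr$out$h, pr$out$w)
  list(out = out,
       cache = list(p = p$cache, b = b$cache, e = e$cache, g = g$cache,
                    pr = pr$cache),
       run = list(bn = b$run))
}

stem_backward <- function(cache, dout, need_dx = FALSE) {
  dpr <- conv_backward(cache$pr, dout)
  dg <- gelu_backward(cache$g, dpr$dx$x)
  de <- conv_backward(cache$e, fmap(dg, dpr$dx$n, dpr$dx$h, dpr$dx$w))
  # B feeds both the bottleneck branch and the residual
  dB <- fmap(de$dx$x + dout$x, dout$n, dout$h, dout$w)
  db <- bn_backward(cache$b, dB)
  dp <- conv_backward(cache$p, db$dx, need_dx = need_dx)
  list(dx = dp$dx,
       grads = list(patch = list(dW = dp$dW, db = dp$db),
                    bn = list(dgamma = db$dgamma, dbeta = db$dbeta),
                    expand = list(dW = de$dW, db = de$db),
                    project = list(dW = dpr$dW, db = dpr$db)))
}

# ---- pooling-based attention ----------------------------------------------
# B = BN(x), one shared instance;
# gate   = sigmoid( avg3x3(B) * max3x3(B) )        (element-wise product)
# concat = [gate, B]                               (gate in low channels)
# out    = Conv1x1_F( GELU( avg3x3(concat) ) ) + B
# All 3x3 pools stride 1, pad 1 (spatial size preserved).

init_attention <- function(f) {
  list(bn = bn_init(f), project = conv_init(conv_spec(1L, 1L, 2L * f, f)))
}

#' Pooling-based attention
#'
#' Parameter-free token mixing: the sigmoid of the element-wise product of
#' 3x3 average- and max-pooled normalized activations forms a gate in (0,1),
#' which is depth-concatenated with the normalized input, average-pooled
#' again, passed through GELU and a 1x1 projection, and added residually.
#' Spatial size and channel count are preserved.
#'
#' @inheritParams patchify_stem
#' @return list(out, cache, run) as for [patchify_stem()].
#' @export
pooling_attention <- function(fm, par, training = FALSE, eps = 1e-5,
                              momentum = 0.1) {
  if (fm$h < 3L || fm$w < 3L)
    stop(sprintf("pooling attention needs spatial size >= 3, got %dx%d",
                 fm$h, fm$w), call. = FALSE)
  b <- bn_forward(fm, par$bn, training, eps, momentum)
  av <- avgpool_forward(b$out, 3L, 1L, 1L)
  mx <- maxpool_forward(b$out, 3L, 1L, 1L)
  prod_ <- av$out$x * mx$out$x
  gate <- 1 / (1 + exp(-prod_))
  cat_ <- fmap(cbind(gate, b$out$x), fm$n, fm$h, fm$w)
  av2 <- avgpool_forward(cat_, 3L, 1L, 1L)
  g <- gelu_forward(av2$out$x)
  ge <- fmap(g$out, fm$n, fm$h, fm$w)
  pr <- conv_forward(ge, par$project)
  out <- fmap(pr$out$x + b$out$x, fm$n, fm$h, fm$w)
  list(out = out,
       cache = list(b = b$cache, av = av$cache, mx = mx$cache,
                    avv = av$out$x, mxv = mx$out$x, gate = gate,
                    av2 = av2$cache, g = g$cache, pr = pr$cache,
                    f = ncol(fm$x), n = fm$n, h = fm$h, w = fm$w),
       run = list(bn = b$run))
}

attention_backward <- function(cache, dout) {
  f <- cache$f
  dpr <- conv_backward(cache$pr, dout)
  dg <- gelu_backward(cache$g, dpr$dx$x)
  dcat <- avgpool_backward(cache$av2, fmap(dg, cache$n, cache$h, cache$w))
  dgate <- dcat$x[, seq_len(f), drop = FALSE]
  dB_cat <- dcat$x[, f + seq_len(f), drop = FALSE]
  dprod <- dgate * cache$gate * (1 - cache$gate)
  dav <- fmap(dprod * cache$mxv, cache$n, cache$h, cache$w)
  dmx <- fmap(dprod * cache$avv, cache$n, cache$h, cache$w)
  dB_av <- avgpool_backward(cache$av, dav)
  dB_mx <- maxpool_backward(cache$mx, dmx)
  dB <- fmap(dout$x + dB_cat + dB_av$x + dB_mx$x, cache$n, cache$h, cache$w)
  db <- bn_backward(cache$b, dB)
  list(dx = db$dx,
       grads = list(bn = list(dgamma = db$dgamma, dbeta = db$dbeta),
                    project = list(dW = dpr$dW, db = dpr$db)))
}

# ---- inverted bottleneck ---------------------------------------------------
# out = Conv1x1_F( GELU( GConv1x1_{4F}( BN(x) ) ) ) + x

init_bottleneck <- function(f, groups = 4L) {
  list(bn = bn_init(f),
       expand = conv_init(conv_spec(1L, 1L, f, 4L * f, groups = groups)),
       project = conv_init(conv_spec(1L, 1L, 4L * f, f)))
}

#' Inverted bottleneck
#'
#' Transformer-style feed-forward analogue: batch normalization, grouped 1x1
#' expansion to 4F channels, GELU, 1x1 projection back to F, plus the
#' identity shortcut. Spatial size and channel count are preserved.
#'
#' @inheritParams patchify_stem
#' @return list(out, cache, run) as for [patchify_stem()].
#' @export
inverted_bottleneck <- function(fm, par, training = FALSE, eps = 1e-5,
                                momentum = 0.1) {
  b <- bn_forward(fm, par$bn, training, eps, momentum)
  e <- conv_forward(b$out, par$expand)
  g <- gelu_forward(e$out$x)
  ge <- fmap(g$out, fm$n, fm$h, fm$w)
  pr <- conv_forward(ge, par$project)
  out <- fmap(pr$out$x + fm$x, fm$n, fm$h, fm$w)
  list(out = out,
       cache = list(b = b$cache, e = e$cache, g = g$cache, pr = pr$cache),
       run = list(bn = b$run))
}

bottleneck_backward <- function(cache, dout) {
  dpr <- conv_backward(cache$pr, dout)
  dg <- gelu_backward(cache$g, dpr$dx$x)
  de <- conv_backward(cache$e, fmap(dg, dout$n, dout$h, dout$w))
  db <- bn_backward(cache$b, de$dx)
  dx <- fmap(db$dx$x + dout$x, dout$n, dout$h, dout$w)
  list(dx = dx,
       grads = list(bn = list(dgamma = db$dgamma, dbeta = db$dbeta),
                    expand = list(dW = de$dW, db = de$db),
                    project = list(dW = dpr$dW, db = dpr$db)))
}

# ---- TNV2 block ------------------------------------------------------------

init_tnv2_block <- function(f, expansion_groups = 4L) {
  list(att = init_attention(f),
       ib = init_bottleneck(f, groups = expansion_groups))
}

#' TNV2 block
#'
#' The main feature generator: [pooling_attention()] followed by
#' [inverted_bottleneck()]. Shape-preserving; holds exactly three
#' parameterized convolutions (2F->F, F->4F grouped, 4F->F).
#'
#' @inheritParams patchify_stem
#' @return list(out, cache, run) as for [patchify_stem()].
#' @export
tnv2_block <- function(fm, par, training = FALSE, eps = 1e-5, momentum = 0.1) {
  a <- pooling_attention(fm, par$att, training, eps, momentum)
  i <- inverted_bottleneck(a$out, par$ib, training, eps, momentum)
  list(out = i$out, cache = list(att = a$cache, ib = i$cache),
       run = list(att = a$run, ib = i$run))
}

tnv2_block_backward <- function(cache, dout) {
  di <- bottleneck_backward(cache$ib, dout)
  da <- attention_backward(cache$att, di$dx)
  list(dx = da$dx, grads = list(att = da$grads, ib = di$grads))
}

# ---- hybrid downsampling ---------------------------------------------------
# out = GELU( [avg2x2s2(x), max2x2s2(x)] + GConv2x2s2_{2F}(x) )

init_downsample <- function(f, groups = 2L) {
  list(conv = conv_init(conv_spec(2L, 2L, f, 2L * f, groups = groups)))
}

#' Hybrid downsampling
#'
#' Halves the spatial resolution while doubling the channels: the channel
#' concatenation of 2x2 stride-2 average and max pooling (average in the low
#' channels) is added to a 2x2 stride-2 grouped convolution, followed by one
#' GELU. Odd spatial sizes are an error (no implicit padding).
#'
#' @inheritParams patchify_stem
#' @return list(out, cache, run); `out` is (H/2)x(W/2)x2F.
#' @export
hybrid_downsample <- function(fm, par, training = FALSE, eps = 1e-5,
                              momentum = 0.1) {
  if (fm$h %% 2L != 0L || fm$w %% 2L != 0L)
    stop(sprintf("hybrid downsampling needs even spatial size, got %dx%d",
                 fm$h, fm$w), call. = FALSE)
  av <- avgpool_forward(fm, 2L, 2L, 0L)
  mx <- maxpool_forward(fm, 2L, 2L, 0L)
  cv <- conv_forward(fm, par$conv)
  S <- cbind(av$out$x, mx$out$x) + cv$out$x
  g <- gelu_forward(S)
  list(out = fmap(g$out, cv$out$n, cv$out$h, cv$out$w),
       cache = list(av = av$cache, mx = mx$cache, cv = cv$cache, g = g$cache,
                    f = ncol(fm$x), no = cv$out$n, ho = cv$out$h,
                    wo = cv$out$w),
       run = list())
}

downsample_backward <- function(cache, dout) {
  f <- cache$f
  dS <- gelu_backward(cache$g, dout$x)
  dSf <- fmap(dS, cache$no, cache$ho, cache$wo)
  dcv <- conv_backward(cache$cv, dSf)
  dav <- avgpool_backward(cache$av,
                          fmap(dS[, seq_len(f), drop = FALSE],
                               cache$no, cache$ho, cache$wo))
  dmx <- maxpool_backward(cache$mx,
                          fmap(dS[, f + seq_len(f), drop = FALSE],
                               cache$no, cache$ho, cache$wo))
  dx <- fmap(dcv$dx$x + dav$x + dmx$x, dav$n, dav$h, dav$w)
  list(dx = dx, grads = list(conv = list(dW = dcv$dW, db = dcv$db)))
}

# ---- classification head ---------------------------------------------------

init_head <- function(features, num_classes) {
  if (num_classes < 2L)
    stop("classification head needs at least 2 classes", call. = FALSE)
  list(fc = fc_init(features, num_classes))
}

#' Classification head
#'
#' Global average pooling flattens the final tensor to one feature per
#' channel, a fully connected layer maps to class scores, and a softmax
#' produces probabilities (each row sums to one).
#'
#' @inheritParams patchify_stem
#' @param par head weights (element `head` of a built network).
#' @return list with `probs` (n x classes), `logits`, and `cache`.
#' @export
classification_head <- function(fm, par) {
  g <- gap_forward(fm)
  fc <- fc_forward(g$out, par$fc)
  list(probs = softmax_rows(fc$out), logits = fc$out,
       cache = list(g = g$cache, fc = fc$cache))
}

head_backward <- function(cache, dlogits) {
  dfc <- fc_backward(cache$fc, dlogits)
  dx <- gap_backward(cache$g, dfc$dx)
  list(dx = dx, grads = list(fc = list(dW = dfc$dW, db = dfc$db)))
}
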