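# Architectural operators: shapes, closed-form special cases, and
# equivalence with loop-based oracles.

zero_convs <- function(par) {
  for (k in names(par)) {
    if (!is.null(par[[k]]$W)) {
      par[[k]]$W[] <- 0
      if (!is.null(par[[k]]$b)) par[[k]]$b[] <- 0
    } else if (is.list(par[[k]]) && is.null(par[[k]]$gamma)) {
      par[[k]] <- zero_convs(par[[k]])
    }
  }
  par
}

test_that("patchify stem maps 224x224x3 to 56x56x96 and zeros propagate", {
  par <- tnv2:::init_stem(96L)
  fm <- as_fmap(array(0, c(224, 224, 3)))
  out <- patchify_stem(fm, zero_convs(par))$out
  expect_equal(dim(out), c(1L, 56L, 56L, 96L))
  # zero input, zero conv biases, identity BN: every branch stays zero
  expect_true(all(out$x == 0))
  expect_error(patchify_stem(as_fmap(array(0, c(30, 30, 3))), par),
               "divisible by 4")
  expect_error(patchify_stem(as_fmap(array(0, c(224, 224, 2))), par),
               "channels")
})

test_that("single-patch stem embedding equals the brute-force convolution", {
  set.seed(11)
  par <- tnv2:::init_stem(96L)
  par$expand <- zero_convs(list(e = par$expand))$e  # isolate the patch path
  par$project <- zero_convs(list(p = par$project))$p
  a <- array(runif(4 * 4 * 3), c(4, 4, 3))
  out <- patchify_stem(as_fmap(a), par)$out
  expect_equal(dim(out), c(1L, 1L, 1L, 96L))
  # fresh BN is the near-identity map x / sqrt(1 + eps) in evaluation mode
  s <- 1 / sqrt(1 + 1e-5)
  ref <- oracle_conv2d(a, par$patch$W, par$patch$b, k = 4, stride = 4)
  expect_equal(as.numeric(out$x), s * as.numeric(ref[1, 1, ]),
               tolerance = 1e-10)
})

test_that("pooling attention: gate range, zero-input value, shape, errors", {
  set.seed(12)
  par <- tnv2:::init_attention(4L)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- pooling_attention(as_fmap(a), par)
  expect_equal(dim(r$out), c(1L, 8L, 8L, 4L))
  expect_true(all(r$cache$gate > 0 & r$cache$gate < 1))
  # zero input with identity BN: product of pools is 0, sigmoid(0) = 0.5
  rz <- pooling_attention(as_fmap(array(0, c(6, 6, 4))), par)
  expect_true(all(rz$cache$gate == 0.5))
  expect_error(pooling_attention(as_fmap(array(0, c(2, 5, 4))), par), ">= 3")
})

test_that("center-pixel gate of a single hotspot matches the hand pooling", {
  par <- tnv2:::init_attention(1L)
  a <- array(0, c(4, 4, 1)); a[2, 2, 1] <- 1
  r <- pooling_attention(as_fmap(a), par)
  gate <- matrix(r$cache$gate, 4, 4, byrow = TRUE)
  # fresh BN scales by s = 1/sqrt(1 + eps) before the pools;
  # center (2,2): avg over its full 3x3 window is s/9, max is s
  s <- 1 / sqrt(1 + 1e-5)
  expect_equal(gate[2, 2], 1 / (1 + exp(-(s / 9) * s)), tolerance = 1e-12)
  ref_av <- oracle_pool(s * a, 3, 1, 1, "avg")
  ref_mx <- oracle_pool(s * a, 3, 1, 1, "max")
  ref_gate <- 1 / (1 + exp(-(ref_av * ref_mx)))
  expect_equal(gate, ref_gate[, , 1], tolerance = 1e-12)
})

test_that("inverted bottleneck: shape, residual identity, scalar oracle", {
  set.seed(13)
  par <- tnv2:::init_bottleneck(4L)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- inverted_bottleneck(as_fmap(a), par)
  expect_equal(dim(r$out), c(1L, 8L, 8L, 4L))
  expect_equal(ncol(r$cache$e$par$W), 16L)      # expansion ratio exactly 4
  # zero convolutions: the residual path makes the block the identity
  rz <- inverted_bottleneck(as_fmap(a), zero_convs(par))
  expect_equal(fmap_to_array(rz$out)[, , , 1], a, tolerance = 1e-12)
  # 1x1x4 input, groups 1: explicit affine-GELU-affine chain
  par1 <- tnv2:::init_bottleneck(4L, groups = 1L)
  x <- array(rnorm(4), c(1, 1, 4))
  r1 <- inverted_bottleneck(as_fmap(x), par1)
  v <- as.numeric(x[1, 1, ])
  e <- drop((v / sqrt(1 + 1e-5)) %*% par1$expand$W) + par1$expand$b
  ref <- drop((e * pnorm(e)) %*% par1$project$W) + par1$project$b + v
  expect_equal(as.numeric(r1$out$x), ref, tolerance = 1e-10)
})

test_that("TNV2 block preserves 28x28x192 and carries 7F^2+10F parameters", {
  par <- tnv2:::init_tnv2_block(192L)
  fm <- as_fmap(array(rnorm(28 * 28 * 192), c(28, 28, 192)))
  out <- tnv2_block(fm, par)$out
  expect_equal(dim(out), c(1L, 28L, 28L, 192L))
  count <- function(p) {
    tot <- 0
    for (k in names(p)) {
      if (!is.null(p[[k]]$W)) tot <- tot + length(p[[k]]$W) + length(p[[k]]$b)
      else if (!is.null(p[[k]]$gamma))
        tot <- tot + length(p[[k]]$gamma) + length(p[[k]]$beta)
      else tot <- tot + count(p[[k]])
    }
    tot
  }
  for (f in c(96L, 192L)) {
    expect_identical(count(tnv2:::init_tnv2_block(f)), 7 * f^2 + 10 * f)
  }
  expect_identical(count(tnv2:::init_tnv2_block(96L)), 65472)
})

test_that("hybrid downsampling halves space, doubles channels, and a
           constant input with zero convolutions gives GELU(c) everywhere", {
  set.seed(14)
  par <- tnv2:::init_downsample(4L)
  a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- hybrid_downsample(as_fmap(a), par)
  expect_equal(dim(r$out), c(1L, 4L, 4L, 8L))
  cval <- 0.7
  rz <- hybrid_downsample(as_fmap(array(cval, c(4, 4, 2))),
                          zero_convs(tnv2:::init_downsample(2L)))
  expect_equal(as.numeric(rz$out$x), rep(cval * pnorm(cval), 4 * 4),
               tolerance = 1e-12)
  expect_error(hybrid_downsample(as_fmap(array(0, c(5, 6, 4))), par), "even")
})

test_that("classification head: 768 pooled features, uniform under zero
           weights, softmax matches exp/normalize", {
  set.seed(15)
  par <- tnv2:::init_head(768L, 3L)
  a <- array(rnorm(7 * 7 * 768), c(7, 7, 768))
  g <- tnv2:::gap_forward(as_fmap(a))
  expect_length(g$out, 768L)
  r <- classification_head(as_fmap(a), par)
  expect_equal(sum(r$probs), 1, tolerance = 1e-6)
  expect_true(all(r$probs > 0 & r$probs < 1))
  ref <- oracle_head(a, par)
  expect_equal(as.numeric(r$probs), as.numeric(ref), tolerance = 1e-6)
  parz <- par; parz$fc$W[] <- 0; parz$fc$b[] <- 0
  expect_equal(as.numeric(classification_head(as_fmap(a), parz)$probs),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(tnv2:::init_head(768L, 1L), "at least 2")
})

test_that("every block matches its loop-based oracle on small inputs", {
  set.seed(16)
  for (trial in 1:3) {
    a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    par <- randomize_bn(tnv2:::init_attention(4L))
    got <- fmap_to_array(pooling_attention(as_fmap(a), par)$out)[, , , 1]
    expect_equal(got, oracle_attention(a, par), tolerance = 1e-5)
    par <- randomize_bn(tnv2:::init_bottleneck(4L))
    got <- fmap_to_array(inverted_bottleneck(as_fmap(a), par)$out)[, , , 1]
    expect_equal(got, oracle_bottleneck(a, par), tolerance = 1e-5)
    par <- tnv2:::init_downsample(4L)
    got <- fmap_to_array(hybrid_downsample(as_fmap(a), par)$out)[, , , 1]
    expect_equal(got, oracle_downsample(a, par), tolerance = 1e-5)
    a3 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    par <- randomize_bn(tnv2:::init_stem(4L))
    got <- fmap_to_array(patchify_stem(as_fmap(a3), par)$out)[, , , 1]
    expect_equal(got, oracle_stem(a3, par), tolerance = 1e-5)
  }
})

test_that("blocks preserve finiteness over randomized weights and inputs", {
  set.seed(17)
  for (trial in 1:100) {
    f <- sample(c(2L, 4L), 1)
    h <- sample(4:8, 1) * 2L
    a <- array(rnorm(h * h * f, sd = runif(1, 0.1, 3)), c(h, h, f))
    fm <- as_fmap(a)
    block <- sample(3, 1)
    out <- switch(block,
      pooling_attention(fm, randomize_bn(tnv2:::init_attention(f)))$out,
      inverted_bottleneck(fm, randomize_bn(tnv2:::init_bottleneck(f, 2L)))$out,
      hybrid_downsample(fm, tnv2:::init_downsample(f))$out)
    expect_true(all(is.finite(out$x)))
    if (block <= 2) expect_equal(dim(out), dim(fm))
    else expect_equal(dim(out), c(1L, h / 2L, h / 2L, 2L * f))
  }
})
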