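# Network assembly, shape tracing, parameter counting, checkpoints.

test_that("default build has 4 TNV2 stages, 3 downsamplings, stem and head;
           repeats extend blocks without changing stage shapes", {
  cfg <- tnv2_config(num_classes = 10L)
  model <- build_network(cfg)
  nm <- names(model$params)
  expect_length(grep("^s\\d\\.b\\d$", nm), 4L)
  expect_length(grep("^down\\d$", nm), 3L)
  expect_true(all(c("stem", "head") %in% nm))
  tr1 <- trace_shapes(cfg)
  cfg2 <- tnv2_config(num_classes = 10L, repeats = c(2L, 2L, 2L, 2L))
  expect_length(grep("^s\\d\\.b\\d$", names(build_network(cfg2)$params)), 8L)
  tr2 <- trace_shapes(cfg2)
  # per-stage output shapes are unchanged by repeats
  key <- function(tr) unique(tr[, c("height", "width", "channels")])
  expect_equal(key(tr2), key(tr1), ignore_attr = TRUE)
})

test_that("config validation names the offence", {
  expect_error(tnv2_config(filters = c(96L, 180L)), "double")
  expect_error(tnv2_config(filters = c(6L, 12L)), "stage 1")
  expect_error(tnv2_config(num_classes = 1L), "num_classes")
  expect_error(tnv2_config(input_size = c(100L, 100L, 3L)), "divisible")
})

test_that("shape trace matches the published transition table and halves
           with a halved input", {
  tr <- trace_shapes(tnv2_config(num_classes = 10L))
  shp <- function(stage) unlist(tr[tr$stage == stage,
                                   c("height", "width", "channels")],
                                use.names = FALSE)
  expect_equal(shp("stem"), c(56, 56, 96))
  expect_equal(shp("s1.b1"), c(56, 56, 96))
  expect_equal(shp("down1"), c(28, 28, 192))
  expect_equal(shp("s2.b1"), c(28, 28, 192))
  expect_equal(shp("down2"), c(14, 14, 384))
  expect_equal(shp("s3.b1"), c(14, 14, 384))
  expect_equal(shp("down3"), c(7, 7, 768))
  expect_equal(shp("s4.b1"), c(7, 7, 768))
  expect_equal(shp("gap"), c(1, 1, 768))
  # stride arithmetic is scale-equivariant: doubling the input doubles
  # every spatial extent (only the pooled/head rows are size-free)
  tr2 <- trace_shapes(tnv2_config(num_classes = 10L,
                                  input_size = c(448L, 448L, 3L)))
  sp <- tr2$stage %in% c("gap", "head")
  expect_equal(tr2$height[!sp], 2L * tr$height[!sp])
  expect_equal(tr2$width[!sp], 2L * tr$width[!sp])
})

test_that("trace agrees with a runtime shape probe, stage by stage", {
  cfg <- tiny_net()
  model <- build_network(cfg)
  tr <- trace_shapes(cfg)
  fm <- as_fmap(array(rnorm(32 * 32 * 3), c(32, 32, 3)))
  for (st in tnv2:::stage_plan(cfg)) {
    r <- switch(st$kind,
      stem = patchify_stem(fm, model$params$stem),
      tnv2 = tnv2_block(fm, model$params[[st$name]]),
      down = hybrid_downsample(fm, model$params[[st$name]]))
    fm <- r$out
    row <- tr[tr$stage == st$name, ]
    expect_equal(dim(fm)[2:4], c(row$height, row$width, row$channels))
  }
})

test_that("closed-form counts equal weight enumeration on randomized
           configurations and scale as expected", {
  set.seed(21)
  for (trial in 1:20) {
    ns <- sample(2:4, 1)
    f1 <- sample(c(4L, 8L, 12L), 1)
    cfg <- tnv2_config(filters = f1 * 2L^(0:(ns - 1L)),
                       repeats = sample(1:2, ns, replace = TRUE),
                       num_classes = sample(2:5, 1),
                       input_size = c(96L, 96L, 3L), seed = trial)
    expect_identical(enumerate_parameters(cfg),
                     as.integer(count_parameters(cfg)$total))
  }
  # only the FC layer depends on the class count
  d <- count_parameters(tnv2_config(num_classes = 1000L))$total -
    count_parameters(tnv2_config(num_classes = 10L))$total
  expect_equal(d, 768 * 990 + 990)
  # doubling all widths roughly quadruples the quadratic terms
  r <- count_parameters(tnv2_config(filters = c(192L, 384L, 768L, 1536L),
                                    num_classes = 10L))$total /
    count_parameters(tnv2_config(num_classes = 10L))$total
  expect_gt(r, 3.5)
  expect_lt(r, 4.2)
})

test_that("forward pass is a probability vector; evaluation mode is
           deterministic and checkpoints round-trip bit-exactly", {
  cfg <- tiny_net()
  model <- build_network(cfg)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  f1 <- tnv2_forward(model, x)
  expect_equal(rowSums(f1$probs), 1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(f1$probs > 0 & f1$probs < 1))
  f2 <- tnv2_forward(model, x)
  expect_identical(f1$probs, f2$probs)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  f3 <- tnv2_forward(load_checkpoint(path), x)
  expect_identical(f1$probs, f3$probs)
  unlink(path)
  # same seed, same construction
  expect_identical(build_network(cfg)$params$stem$patch$W,
                   model$params$stem$patch$W)
})
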