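# Shared fixtures, memoized so expensive objects are built once per session.
#
# The scaled-down training study: 64 synthetic pressure images (32 per
# class, generator defaults, data seed 101), width-scaled network
# (filters 8/16/32/64) at the full 224x224 input, and the published recipe
# with batch size 16. Training seeds are fixed at 1, 2, 3.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

study_set <- function() {
  memo("study_set", generate_pressure_images(n_per_class = 32L, seed = 101L))
}

study_net <- function() {
  tnv2_config(filters = c(8L, 16L, 32L, 64L), num_classes = 2L)
}

study_fit <- function(seed) {
  memo(paste0("fit_seed_", seed),
       tnv2_fit(study_set(), net = study_net(),
                cfg = tnv2_train_config(batch_size = 16L, seed = seed)))
}

# small configuration for fast structural tests
tiny_net <- function(classes = 2L, seed = 7L) {
  tnv2_config(filters = c(4L, 8L), repeats = c(1L, 1L),
              num_classes = classes, input_size = c(32L, 32L, 3L),
              seed = seed)
}

# image set with deterministic pseudo-random pixels, no generator involved
dummy_set <- function(n_per_class, size = 16L, classes = c("a", "b"),
                      seed = 99L) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  imgs <- array(runif(size * size * 3 * n), c(size, size, 3L, n))
  tnv2_imageset(imgs, rep(seq_along(classes), each = n_per_class), classes)
}
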