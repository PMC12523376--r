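#' Network configuration
#'
#' Describes a TurkerNeXtV2 variant: the stage width schedule `filters`
#' (strictly doubling, default `c(96, 192, 384, 768)`), the per-stage TNV2
#' repeat counts (default one each), the class count, the grouped-convolution
#' policy, the input geometry, batch-norm constants, and the seed used for
#' weight initialization (He fan-in normal for convolutions, zero biases,
#' unit-scale/zero-shift batch norm).
#'
#' @param filters integer vector of stage widths; each stage doubles the
#'   previous one (the hybrid downsampling doubles channels structurally).
#' @param repeats integer vector, same length as `filters`; TNV2 blocks per
#'   stage.
#' @param num_classes number of output classes (>= 2).
#' @param groups list with `stem`, `expansion`, and `downsample` group counts
#'   for the grouped convolutions.
#' @param input_size `c(height, width, channels)`; height and width must be
#'   divisible by `4 * 2^(stages - 1)` so every downsampling stage sees an
#'   even size.
#' @param bn_eps,bn_momentum batch-norm epsilon and running-statistics
#'   momentum.
#' @param seed integer seed for weight initialization.
#' @return An object of class `"tnv2_config"`.
#' @export
tnv2_config <- function(filters = c(96L, 192L, 384L, 768L),
                        repeats = rep(1L, length(filters)),
                        num_classes = 2L,
                        groups = list(stem = 4L, expansion = 4L,
                                      downsample = 2L),
                        input_size = c(224L, 224L, 3L),
                        bn_eps = 1e-5, bn_momentum = 0.1, seed = 1L) {
  filters <- as.integer(filters); repeats <- as.integer(repeats)
  if (length(filters) < 1L || length(filters) != length(repeats))
    stop("filters and repeats must be non-empty and of equal length",
         call. = FALSE)
  if (any(repeats < 1L)) stop("repeats must all be >= 1", call. = FALSE)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  if (length(filters) > 1L &&
      any(filters[-1L] != 2L * filters[-length(filters)]))
    stop("stage widths must double between consecutive stages", call. = FALSE)
  for (s in seq_along(filters)) {
    f <- filters[s]
    if (f %% groups$expansion != 0L || (4L * f) %% groups$expansion != 0L)
      stop(sprintf("stage %d width %d incompatible with expansion groups %d",
                   s, f, groups$expansion), call. = FALSE)
    if (s < length(filters) && f %% groups$downsample != 0L)
      stop(sprintf("stage %d width %d incompatible with downsample groups %d",
                   s, f, groups$downsample), call. = FALSE)
  }
  if (filters[1L] %% groups$stem != 0L)
    stop("stem width incompatible with stem groups", call. = FALSE)
  need <- 4L * 2L^(length(filters) - 1L)
  if (input_size[1L] %% need != 0L || input_size[2L] %% need != 0L)
    stop(sprintf("input size %dx%d must be divisible by %d",
                 input_size[1L], input_size[2L], need), call. = FALSE)
  if (min(input_size[1:2]) %/% need < 3L)
    stop(sprintf(
      "input size %dx%d leaves the last stage below the 3x3 pooling minimum",
      input_size[1L], input_size[2L]), call. = FALSE)
  structure(list(filters = filters, repeats = repeats,
                 num_classes = as.integer(num_classes), groups = groups,
                 input_size = as.integer(input_size),
                 bn_eps = bn_eps, bn_momentum = bn_momentum,
                 seed = as.integer(seed)),
            class = "tnv2_config")
}

#' @export
print.tnv2_config <- function(x, ...) {
  cat("TurkerNeXtV2 configuration\n")
  cat("  filters: ", paste(x$filters, collapse = ", "), "\n", sep = "")
  cat("  repeats: ", paste(x$repeats, collapse = ", "), "\n", sep = "")
  cat(sprintf("  classes: %d   input: %dx%dx%d   seed: %d\n", x$num_classes,
              x$input_size[1], x$input_size[2], x$input_size[3], x$seed))
  cat(sprintf("  groups:  stem %d, expansion %d, downsample %d\n",
              x$groups$stem, x$groups$expansion, x$groups$downsample))
  invisible(x)
}

#' Build a TurkerNeXtV2 network
#'
#' Instantiates all weights for the configured variant:
#' stem -> (TNV2 x R1) -> down -> (TNV2 x R2) -> ... -> head. Construction is
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [tnv2_config()].
#' @return An object of class `"tnv2_model"`: the config plus the nested
#'   named weight list.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "tnv2_config"))
  ns <- length(cfg$filters)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  params <- list(stem = init_stem(cfg$filters[1L], cfg$input_size[3L],
                                  groups = cfg$groups$stem))
  for (s in seq_len(ns)) {
    for (b in seq_len(cfg$repeats[s]))
      params[[sprintf("s%d.b%d", s, b)]] <-
        init_tnv2_block(cfg$filters[s], cfg$groups$expansion)
    if (s < ns)
      params[[sprintf("down%d", s)]] <-
        init_downsample(cfg$filters[s], cfg$groups$downsample)
  }
  params$head <- init_head(cfg$filters[ns], cfg$num_classes)
  structure(list(cfg = cfg, params = params), class = "tnv2_model")
}

#' @export
print.tnv2_model <- function(x, ...) {
  pc <- count_parameters(x$cfg)
  cat(sprintf("TurkerNeXtV2 model: %d stages, %d classes, %s trainable parameters\n",
              length(x$cfg$filters), x$cfg$num_classes,
              format(pc$total, big.mark = ",")))
  invisible(x)
}

# ordered stage walk shared by forward/backward/tracing
stage_plan <- function(cfg) {
  ns <- length(cfg$filters)
  plan <- list(list(kind = "stem", name = "stem"))
  for (s in seq_len(ns)) {
    for (b in seq_len(cfg$repeats[s]))
      plan[[length(plan) + 1L]] <-
        list(kind = "tnv2", name = sprintf("s%d.b%d", s, b), stage = s)
    if (s < ns)
      plan[[length(plan) + 1L]] <-
        list(kind = "down", name = sprintf("down%d", s), stage = s)
  }
  plan
}

#' Forward pass
#'
#' Runs a batch through the network. In training mode batch-norm uses batch
#' statistics and the updated running statistics are returned; in evaluation
#' mode the stored running statistics are used, making the pass deterministic.
#'
#' @param model a `"tnv2_model"`.
#' @param fm an [fmap] batch (or an image array accepted by [as_fmap()]).
#' @param training logical.
#' @param keep_cache keep per-layer caches for a backward pass.
#' @return list with `probs`, `logits`, `features` (last-stage [fmap], the
#'   Grad-CAM target), and when requested `caches` and `run` (updated
#'   batch-norm statistics, named like the weight list).
#' @export
tnv2_forward <- function(model, fm, training = FALSE, keep_cache = FALSE) {
  if (!inherits(fm, "fmap")) fm <- as_fmap(fm)
  cfg <- model$cfg
  plan <- stage_plan(cfg)
  caches <- if (keep_cache) vector("list", length(plan) + 1L) else NULL
  run <- list()
  for (i in seq_along(plan)) {
    st <- plan[[i]]
    par <- model$params[[st$name]]
    r <- switch(st$kind,
      stem = patchify_stem(fm, par, training, cfg$bn_eps, cfg$bn_momentum),
      tnv2 = tnv2_block(fm, par, training, cfg$bn_eps, cfg$bn_momentum),
      down = hybrid_downsample(fm, par, training, cfg$bn_eps, cfg$bn_momentum))
    fm <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (training && length(r$run)) run[[st$name]] <- r$run
  }
  hd <- classification_head(fm, model$params$head)
  if (keep_cache) caches[[length(plan) + 1L]] <- hd$cache
  list(probs = hd$probs, logits = hd$logits, features = fm,
       caches = caches, run = run, plan = plan)
}

# Backward pass from d(loss)/d(logits); returns grads named like params.
tnv2_backward <- function(model, fwd, dlogits) {
  plan <- fwd$plan
  grads <- list()
  hb <- head_backward(fwd$caches[[length(plan) + 1L]], dlogits)
  grads$head <- hb$grads
  dfm <- hb$dx
  for (i in rev(seq_along(plan))) {
    st <- plan[[i]]
    r <- switch(st$kind,
      stem = stem_backward(fwd$caches[[i]], dfm, need_dx = FALSE),
      tnv2 = tnv2_block_backward(fwd$caches[[i]], dfm),
      down = downsample_backward(fwd$caches[[i]], dfm))
    grads[[st$name]] <- r$grads
    dfm <- r$dx
  }
  grads
}

# fold updated running statistics back into the weight list
apply_running_stats <- function(model, run) {
  for (name in names(run)) {
    upd <- run[[name]]
    model$params[[name]] <- .apply_run_one(model$params[[name]], upd)
  }
  model
}

.apply_run_one <- function(par, upd) {
  for (k in names(upd)) {
    if (identical(sort(names(upd[[k]])), c("mean", "var"))) {
      par[[k]]$mean <- upd[[k]]$mean
      par[[k]]$var <- upd[[k]]$var
    } else {
      par[[k]] <- .apply_run_one(par[[k]], upd[[k]])
    }
  }
  par
}

#' Symbolic shape trace
#'
#' Walks the stage plan without allocating any weights and reports the output
#' shape of every stage, mirroring the architecture's transition table
#' (stem 56x56x96 -> ... -> 7x7x768 for the default 224x224 input), plus the
#' pooled feature length and class count of the head.
#'
#' @param cfg a [tnv2_config()].
#' @return data.frame of class `"tnv2_shape_trace"` with columns `stage`,
#'   `height`, `width`, `channels`.
#' @export
trace_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "tnv2_config"))
  h <- cfg$input_size[1L]; w <- cfg$input_size[2L]
  rows <- list(list(stage = "input", height = h, width = w,
                    channels = cfg$input_size[3L]))
  h <- h %/% 4L; w <- w %/% 4L
  plan <- stage_plan(cfg)
  for (st in plan) {
    if (st$kind == "stem") {
      ch <- cfg$filters[1L]
    } else if (st$kind == "tnv2") {
      ch <- cfg$filters[st$stage]
    } else {
      h <- h %/% 2L; w <- w %/% 2L
      ch <- cfg$filters[st$stage + 1L]
    }
    rows[[length(rows) + 1L]] <- list(stage = st$name, height = h, width = w,
                                      channels = ch)
  }
  rows[[length(rows) + 1L]] <- list(stage = "gap", height = 1L, width = 1L,
                                    channels = cfg$filters[length(cfg$filters)])
  rows[[length(rows) + 1L]] <- list(stage = "head", height = 1L, width = 1L,
                                    channels = cfg$num_classes)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("tnv2_shape_trace", "data.frame")
  out
}

#' @export
print.tnv2_shape_trace <- function(x, ...) {
  cat("Stage shape trace (H x W x C):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %4d x %4d x %4d\n", x$stage[i], x$height[i],
                x$width[i], x$channels[i]))
  invisible(x)
}

#' Count trainable parameters
#'
#' Closed-form per-layer parameter count: `kh*kw*cin*cout/groups + cout` per
#' convolution (bias included), `2*channels` per batch normalization (scale
#' and shift; running statistics are buffers, not trainable), and
#' `features*classes + classes` for the fully connected head. For the default
#' schedule one TNV2 block at width F costs `7 F^2 + 10 F`.
#'
#' @param cfg a [tnv2_config()].
#' @return list of class `"tnv2_param_count"` with `layers` (data.frame) and
#'   `total`.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "tnv2_config"))
  g <- cfg$groups
  rows <- list()
  add <- function(name, count)
    rows[[length(rows) + 1L]] <<- data.frame(layer = name, params = count)
  f1 <- cfg$filters[1L]; cin <- cfg$input_size[3L]
  add("stem.patch", conv_param_count(conv_spec(4L, 4L, cin, f1)))
  add("stem.bn", 2L * f1)
  add("stem.expand", conv_param_count(conv_spec(1L, 1L, f1, 4L * f1, g$stem)))
  add("stem.project", conv_param_count(conv_spec(1L, 1L, 4L * f1, f1)))
  ns <- length(cfg$filters)
  for (s in seq_len(ns)) {
    f <- cfg$filters[s]
    for (b in seq_len(cfg$repeats[s])) {
      pre <- sprintf("s%d.b%d.", s, b)
      add(paste0(pre, "att.bn"), 2L * f)
      add(paste0(pre, "att.project"),
          conv_param_count(conv_spec(1L, 1L, 2L * f, f)))
      add(paste0(pre, "ib.bn"), 2L * f)
      add(paste0(pre, "ib.expand"),
          conv_param_count(conv_spec(1L, 1L, f, 4L * f, g$expansion)))
      add(paste0(pre, "ib.project"),
          conv_param_count(conv_spec(1L, 1L, 4L * f, f)))
    }
    if (s < ns)
      add(sprintf("down%d.conv", s),
          conv_param_count(conv_spec(2L, 2L, f, 2L * f, g$downsample)))
  }
  add("head.fc", cfg$filters[ns] * cfg$num_classes + cfg$num_classes)
  layers <- do.call(rbind, rows)
  out <- list(layers = layers, total = sum(layers$params))
  class(out) <- "tnv2_param_count"
  out
}

#' @export
print.tnv2_param_count <- function(x, ...) {
  cat(sprintf("Total trainable parameters: %s (%.1f M)\n",
              format(x$total, big.mark = ","), x$total / 1e6))
  invisible(x)
}

#' Enumerate instantiated trainable arrays
#'
#' Independent of the closed form in [count_parameters()]: builds (or takes)
#' a model and sums the lengths of every trainable array (convolution and FC
#' weights and biases, batch-norm scale and shift). Running statistics are
#' excluded.
#'
#' @param model a `"tnv2_model"` or a [tnv2_config()] (built on the fly).
#' @return integer total.
#' @export
enumerate_parameters <- function(model) {
  if (inherits(model, "tnv2_config")) model <- build_network(model)
  total <- 0L
  walk <- function(p) {
    if (is.list(p)) {
      if (!is.null(p$W)) {
        total <<- total + length(p$W) + length(p$b)
      } else if (!is.null(p$gamma)) {
        total <<- total + length(p$gamma) + length(p$beta)
      } else {
        for (q in p) walk(q)
      }
    }
  }
  walk(model$params)
  total
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the full nested weight list
#' (including batch-norm running statistics) and the configuration; loading
#' reproduces bit-identical forward passes.
#'
#' @param model a `"tnv2_model"`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tnv2_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tnv2_model"))
    stop("not a tnv2 checkpoint: ", path, call. = FALSE)
  model
}
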