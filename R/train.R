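#' Training configuration
#'
#' The published recipe: SGD with momentum 0.9, 30 epochs, batch size 128,
#' learning rate 0.01, L2 penalty 1e-4, randomized stratified 80:20
#' train/validation split, every-epoch shuffling, checkpoint selection by
#' best validation accuracy. L2 decay applies to convolution and FC weight
#' matrices only (biases and batch-norm scale/shift are decay-free).
#'
#' @param epochs,batch_size,learning_rate,momentum,l2_penalty scalars.
#' @param split_fraction training fraction used when no validation set is
#'   supplied.
#' @param seed integer; drives the split, shuffling, and weight
#'   initialization.
#' @return list of class `"tnv2_train_config"`.
#' @export
tnv2_train_config <- function(epochs = 30L, batch_size = 128L,
                              learning_rate = 0.01, momentum = 0.9,
                              l2_penalty = 1e-4, split_fraction = 0.8,
                              seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate >= 0,
            momentum >= 0, momentum < 1, l2_penalty >= 0,
            split_fraction > 0, split_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 l2_penalty = l2_penalty, split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "tnv2_train_config")
}

# flatten/modify nested grads & params with matching shape
sgdm_step <- function(params, grads, velocity, lr, momentum, l2) {
  step_one <- function(p, g, v) {
    if (!is.null(p$W)) {
      if (is.null(v)) v <- list(W = 0 * p$W, b = if (!is.null(p$b)) 0 * p$b)
      v$W <- momentum * v$W + (g$dW + l2 * p$W)
      p$W <- p$W - lr * v$W
      if (!is.null(p$b)) {
        v$b <- momentum * v$b + g$db
        p$b <- p$b - lr * v$b
      }
    } else if (!is.null(p$gamma)) {
      if (is.null(v)) v <- list(gamma = 0 * p$gamma, beta = 0 * p$beta)
      v$gamma <- momentum * v$gamma + g$dgamma
      v$beta <- momentum * v$beta + g$dbeta
      p$gamma <- p$gamma - lr * v$gamma
      p$beta <- p$beta - lr * v$beta
    } else {
      if (is.null(v)) v <- list()
      for (k in names(g)) {
        r <- step_one(p[[k]], g[[k]], v[[k]])
        p[[k]] <- r$p; v[[k]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  out_p <- params; out_v <- velocity
  for (name in names(grads)) {
    r <- step_one(params[[name]], grads[[name]], velocity[[name]])
    out_p[[name]] <- r$p; out_v[[name]] <- r$v
  }
  list(params = out_p, velocity = out_v)
}

set_to_fmap <- function(set, idx = seq_len(length(set))) {
  as_fmap(set$images[, , , idx, drop = FALSE])
}

# slice images out of a precomputed whole-set fmap (avoids re-permuting
# arrays every batch)
fmap_slice <- function(fm_all, idx) {
  hw <- fm_all$h * fm_all$w
  rows <- rep((idx - 1L) * hw, each = hw) + seq_len(hw)
  fmap(fm_all$x[rows, , drop = FALSE], length(idx), fm_all$h, fm_all$w)
}

cross_entropy <- function(probs, labels) {
  eps <- 1e-12
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], eps)))
}

evaluate_batched <- function(model, set, batch_size = 32L, fm_all = NULL) {
  n <- length(set)
  if (is.null(fm_all)) fm_all <- set_to_fmap(set)
  probs <- matrix(0, n, model$cfg$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    fwd <- tnv2_forward(model, fmap_slice(fm_all, idx), training = FALSE)
    probs[idx, ] <- fwd$probs
  }
  pred <- max.col(probs, ties.method = "first")
  list(probs = probs, pred = pred,
       loss = cross_entropy(probs, set$labels),
       acc = mean(pred == set$labels))
}

#' Fit a TurkerNeXtV2 classifier
#'
#' The package's central fitting function. Trains the network with SGD with
#' momentum, L2 weight decay, and cross-entropy loss on softmax outputs,
#' shuffling every epoch, and returns the checkpoint of the epoch with the
#' best validation accuracy (earliest epoch on ties) together with the full
#' per-epoch history. Deterministic for a given seed.
#'
#' @param train a [tnv2_imageset]. If `val` is `NULL`, `train` is first split
#'   with [split_train_val()] at `cfg$split_fraction`.
#' @param val optional validation [tnv2_imageset].
#' @param net a [tnv2_config()] (its `num_classes` must match the data) or a
#'   prebuilt `"tnv2_model"` to fine-tune.
#' @param cfg a [tnv2_train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `"tnv2_fit"`: `model` (best checkpoint),
#'   `final_model`, `history` (data.frame with per-epoch loss/accuracy for
#'   both splits), `best_epoch`, `class_names`, `net`, `cfg`.
#' @export
tnv2_fit <- function(train, val = NULL, net = tnv2_config(num_classes = 2L),
                     cfg = tnv2_train_config(), verbose = FALSE) {
  stopifnot(inherits(train, "tnv2_imageset"))
  if (is.null(val)) {
    sp <- split_train_val(train, cfg$split_fraction, seed = cfg$seed)
    train <- sp$train; val <- sp$val
  }
  if (inherits(net, "tnv2_model")) {
    model <- net; netcfg <- model$cfg
  } else {
    netcfg <- net
    netcfg$seed <- cfg$seed
    model <- build_network(netcfg)
  }
  if (netcfg$num_classes != length(train$class_names))
    stop(sprintf("network has %d classes but data has %d",
                 netcfg$num_classes, length(train$class_names)),
         call. = FALSE)
  if (!identical(train$class_names, val$class_names))
    stop("train and validation class names differ", call. = FALSE)
  size <- netcfg$input_size[1:2]
  train <- resize_imageset(train, size)
  val <- resize_imageset(val, size)
  n <- length(train)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  fm_train <- set_to_fmap(train)
  fm_val <- set_to_fmap(val)
  velocity <- list()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, model = model)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      fm <- fmap_slice(fm_train, idx)
      labels <- train$labels[idx]
      fwd <- tnv2_forward(model, fm, training = TRUE, keep_cache = TRUE)
      loss <- cross_entropy(fwd$probs, labels)
      if (!is.finite(loss))
        stop(sprintf("training diverged (loss = %g) at epoch %d", loss,
                     epoch), call. = FALSE)
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") == labels)
      onehot <- matrix(0, length(idx), netcfg$num_classes)
      onehot[cbind(seq_along(idx), labels)] <- 1
      dlogits <- (fwd$probs - onehot) / length(idx)
      grads <- tnv2_backward(model, fwd, dlogits)
      model <- apply_running_stats(model, fwd$run)
      upd <- sgdm_step(model$params, grads, velocity, cfg$learning_rate,
                       cfg$momentum, cfg$l2_penalty)
      model$params <- upd$params
      velocity <- upd$velocity
    }
    ev <- evaluate_batched(model, val, fm_all = fm_val)
    history[epoch, ] <- list(epoch, ep_loss / n, ep_correct / n, ev$loss,
                             ev$acc)
    if (ev$acc > best$acc) best <- list(acc = ev$acc, epoch = epoch,
                                        model = model)
    if (verbose)
      message(sprintf(
        "epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc))
  }
  structure(list(model = best$model, final_model = model, history = history,
                 best_epoch = best$epoch, class_names = train$class_names,
                 net = netcfg, cfg = cfg),
            class = "tnv2_fit")
}

#' @export
print.tnv2_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("TurkerNeXtV2 fit: %d epochs, best epoch %d\n", nrow(h),
              x$best_epoch))
  cat(sprintf("  final train acc %.3f | best val acc %.3f\n",
              h$train_acc[nrow(h)], h$val_acc[x$best_epoch]))
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tnv2_fit <- function(object, ...) {
  h <- object$history
  pc <- count_parameters(object$net)
  cat("TurkerNeXtV2 classifier\n")
  print(object$net)
  cat(sprintf("  trainable parameters: %s\n",
              format(pc$total, big.mark = ",")))
  cat(sprintf("  epochs: %d  batch: %d  lr: %g  momentum: %g  L2: %g\n",
              object$cfg$epochs, object$cfg$batch_size,
              object$cfg$learning_rate, object$cfg$momentum,
              object$cfg$l2_penalty))
  cat(sprintf("  best epoch %d: val acc %.3f (train acc %.3f)\n",
              object$best_epoch, h$val_acc[object$best_epoch],
              h$train_acc[object$best_epoch]))
  invisible(object)
}

#' @export
coef.tnv2_fit <- function(object, ...) object$model$params

#' Plot training history
#'
#' Loss and accuracy per epoch for the training and validation splits.
#'
#' @param x a `"tnv2_fit"`.
#' @param ... unused.
#' @export
plot.tnv2_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "cross-entropy loss", main = "loss")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "accuracy", ylim = c(0, 1), main = "accuracy")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Predict classes for an image set
#'
#' Evaluation-mode forward pass; predicted label is the probability argmax,
#' ties broken toward the lowest class index.
#'
#' @param object a `"tnv2_fit"` (or pass a `"tnv2_model"` to
#'   [predict_model()]).
#' @param newdata a [tnv2_imageset]; resized to the network input size if
#'   needed.
#' @param ... unused.
#' @return list with `probs` (n x k matrix, columns named by class), `labels`
#'   (integer), and `class_names`.
#' @export
predict.tnv2_fit <- function(object, newdata, ...) {
  if (!identical(object$class_names, newdata$class_names))
    stop("checkpoint classes do not match the data", call. = FALSE)
  predict_model(object$model, newdata, object$class_names)
}

#' @rdname predict.tnv2_fit
#' @param model a `"tnv2_model"`.
#' @param set a [tnv2_imageset].
#' @param class_names optional class names for the probability columns.
#' @export
predict_model <- function(model, set, class_names = set$class_names) {
  if (model$cfg$num_classes != length(class_names))
    stop("model/class-name mismatch", call. = FALSE)
  set <- resize_imageset(set, model$cfg$input_size[1:2])
  ev <- evaluate_batched(model, set)
  colnames(ev$probs) <- class_names
  list(probs = ev$probs, labels = ev$pred, class_names = class_names)
}
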