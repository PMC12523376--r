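#' Grad-CAM saliency
#'
#' Gradient-weighted class activation mapping from the last convolutional
#' stage (the output of the final TNV2 block, before global average pooling).
#' The class score is the pre-softmax logit; its gradients with respect to
#' the stage activations are averaged spatially to one weight per channel,
#' the weighted channel sum is rectified (ReLU), bilinearly upsampled to the
#' input resolution, and min-max normalized to `[0, 1]`. A constant raw map
#' (e.g. an all-zero-weight head) yields the all-zeros heat map.
#'
#' @param model a `"tnv2_model"` or `"tnv2_fit"`.
#' @param image an `h x w x 3` array in `[0, 1]` (resized to the network
#'   input size if needed).
#' @param class_index 1-based target class.
#' @return object of class `"tnv2_saliency"`: list with `heat` (input-sized
#'   matrix in `[0, 1]`), `class_index`, `layer`.
#' @export
grad_cam <- function(model, image, class_index) {
  if (inherits(model, "tnv2_fit")) model <- model$model
  stopifnot(inherits(model, "tnv2_model"))
  if (class_index < 1L || class_index > model$cfg$num_classes)
    stop(sprintf("class_index must be in 1..%d", model$cfg$num_classes),
         call. = FALSE)
  size <- model$cfg$input_size[1:2]
  if (!all(dim(image)[1:2] == size))
    image <- resize_image(image, size[1L], size[2L])
  fwd <- tnv2_forward(model, as_fmap(image), training = FALSE,
                      keep_cache = TRUE)
  A <- fwd$features                          # 1 x hs x ws x C fmap
  dlogits <- matrix(0, 1L, model$cfg$num_classes)
  dlogits[1L, class_index] <- 1
  hb <- head_backward(fwd$caches[[length(fwd$plan) + 1L]], dlogits)
  dA <- hb$dx$x                              # (hs*ws) x C gradient
  alpha <- colMeans(dA)                      # spatially averaged gradients
  raw <- drop(A$x %*% alpha)                 # weighted channel sum
  raw <- pmax(raw, 0)                        # ReLU rectification
  m <- matrix(raw, A$h, A$w, byrow = TRUE)   # rows are h (w fastest in fmap)
  if (max(m) > min(m)) {
    m <- (m - min(m)) / (max(m) - min(m))
  } else {
    m <- matrix(0, A$h, A$w)
  }
  heat <- bilinear_upsample(m, size[1L], size[2L])
  structure(list(heat = heat, class_index = as.integer(class_index),
                 layer = sprintf("s%d.b%d", length(model$cfg$filters),
                                 model$cfg$repeats[length(model$cfg$repeats)])),
            class = "tnv2_saliency")
}

# align-corners bilinear interpolation of a matrix to (oh x ow)
bilinear_upsample <- function(m, oh, ow) {
  ih <- nrow(m); iw <- ncol(m)
  if (ih == oh && iw == ow) return(m)
  ry <- if (oh > 1L) (ih - 1) / (oh - 1) else 0
  rx <- if (ow > 1L) (iw - 1) / (ow - 1) else 0
  y <- (seq_len(oh) - 1) * ry
  x <- (seq_len(ow) - 1) * rx
  y0 <- pmin(floor(y), ih - 1 - (ih > 1)) ; fy <- y - y0
  x0 <- pmin(floor(x), iw - 1 - (iw > 1)) ; fx <- x - x0
  y0 <- y0 + 1; x0 <- x0 + 1
  y1 <- pmin(y0 + 1, ih); x1 <- pmin(x0 + 1, iw)
  wy <- matrix(fy, oh, ow); wx <- matrix(fx, oh, ow, byrow = TRUE)
  m[y0, x0] * (1 - wy) * (1 - wx) + m[y1, x0] * wy * (1 - wx) +
    m[y0, x1] * (1 - wy) * wx + m[y1, x1] * wy * wx
}

#' @export
print.tnv2_saliency <- function(x, ...) {
  cat(sprintf("<tnv2_saliency> %dx%d heat map for class %d (layer %s), range [%.3f, %.3f]\n",
              nrow(x$heat), ncol(x$heat), x$class_index, x$layer,
              min(x$heat), max(x$heat)))
  invisible(x)
}

# simple blue -> green -> yellow -> red heat colormap, per-pixel RGB in [0,1]
heat_colors <- function(v) {
  r <- pmin(pmax(2.5 * (v - 0.4), 0), 1)
  g <- pmin(pmax(1.6 * (1 - abs(v - 0.55) / 0.45), 0), 1)
  b <- pmin(pmax(1 - 2.2 * v, 0), 1)
  list(r = r, g = g, b = b)
}

#' Render a saliency overlay
#'
#' Alpha-blends the heat map (heat colormap) over the grayscale image and
#' writes both the raw heat map and the overlay as PNG.
#'
#' @param sal a `"tnv2_saliency"`.
#' @param image the `h x w x 3` input image in `[0, 1]`.
#' @param path_heat,path_overlay output PNG paths (`NULL` to skip either).
#' @param alpha overlay opacity in `[0, 1]`.
#' @return invisibly, the blended `h x w x 3` array.
#' @export
write_saliency <- function(sal, image, path_heat = NULL, path_overlay = NULL,
                           alpha = 0.45) {
  if (!all(dim(image)[1:2] == dim(sal$heat)))
    image <- resize_image(image, nrow(sal$heat), ncol(sal$heat))
  hc <- heat_colors(sal$heat)
  heat_rgb <- array(c(hc$r, hc$g, hc$b), c(dim(sal$heat), 3L))
  blend <- (1 - alpha) * image + alpha * heat_rgb
  blend <- pmin(pmax(blend, 0), 1)
  wr <- function(a, path) {
    e <- EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
    EBImage::writeImage(e, path)
  }
  if (!is.null(path_heat)) wr(heat_rgb, path_heat)
  if (!is.null(path_overlay)) wr(blend, path_overlay)
  invisible(blend)
}

#' @export
plot.tnv2_saliency <- function(x, ...) {
  graphics::image(t(x$heat)[, nrow(x$heat):1], col = grDevices::hcl.colors(64,
                  "inferno"), axes = FALSE, main = sprintf(
                  "Grad-CAM, class %d", x$class_index))
  invisible(x)
}
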