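#' Labeled image sets
#'
#' The container used throughout the package: an `h x w x 3 x n` array of
#' images scaled to `[0, 1]`, integer class labels (1-based, indexing
#' `class_names`), and a split tag.
#'
#' @param images numeric array `h x w x 3 x n`.
#' @param labels integer vector of length n.
#' @param class_names character vector; labels index into it.
#' @param split one of "train", "val", "test", or "" (unset).
#' @return object of class `"tnv2_imageset"`.
#' @export
tnv2_imageset <- function(images, labels, class_names, split = "") {
  d <- dim(images)
  stopifnot(length(d) == 4L, d[3L] == 3L, d[4L] == length(labels),
            all(labels >= 1L), all(labels <= length(class_names)))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names, split = split),
            class = "tnv2_imageset")
}

#' @export
print.tnv2_imageset <- function(x, ...) {
  d <- dim(x$images)
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  cat(sprintf("<tnv2_imageset%s> %d images, %dx%d\n",
              if (nzchar(x$split)) paste0(" ", x$split) else "", d[4L],
              d[1L], d[2L]))
  for (cn in x$class_names) cat(sprintf("  %-16s %d\n", cn, tab[[cn]]))
  invisible(x)
}

#' @export
length.tnv2_imageset <- function(x) dim(x$images)[4L]

subset_imageset <- function(set, idx) {
  tnv2_imageset(set$images[, , , idx, drop = FALSE], set$labels[idx],
                set$class_names, set$split)
}

# bilinear resize of one h x w x c array via EBImage (x/y transposed there)
resize_image <- function(a, h, w) {
  if (dim(a)[1L] == h && dim(a)[2L] == w) return(a)
  e <- EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  r <- EBImage::resize(e, w = w, h = h)
  aperm(as.array(r), c(2L, 1L, 3L))
}

#' Resize every image in a set
#'
#' @param set a [tnv2_imageset].
#' @param size target `c(height, width)`.
#' @export
resize_imageset <- function(set, size) {
  d <- dim(set$images)
  if (d[1L] == size[1L] && d[2L] == size[2L]) return(set)
  out <- array(0, c(size[1L], size[2L], 3L, d[4L]))
  for (i in seq_len(d[4L]))
    out[, , , i] <- resize_image(set$images[, , , i, drop = TRUE],
                                 size[1L], size[2L])
  res <- tnv2_imageset(pmin(pmax(out, 0), 1), set$labels, set$class_names,
                       set$split)
  attr(res, "hotspots") <- attr(set, "hotspots")
  res
}

#' Read a directory-per-class image dataset
#'
#' Expects `root/<class>/<image>.png` (PNG, JPEG, or TIFF). Classes and files
#' are ordered lexicographically, so the set is deterministic. Images are
#' resized to `size`, grayscale is replicated to 3 channels, and values are
#' scaled to `[0, 1]`.
#'
#' @param root dataset root directory.
#' @param size target `c(height, width)` (default 224 x 224).
#' @param split split tag recorded on the set.
#' @return a [tnv2_imageset].
#' @export
read_image_folder <- function(root, size = c(224L, 224L), split = "") {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2L)
    stop("need at least 2 class subdirectories under ", root, call. = FALSE)
  files <- list(); labels <- integer()
  for (ci in seq_along(classes)) {
    fs <- sort(list.files(file.path(root, classes[ci]),
                          pattern = "\\.(png|jpe?g|tiff?)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (length(fs) == 0L)
      stop("empty class directory: ", file.path(root, classes[ci]),
           call. = FALSE)
    files <- c(files, as.list(fs))
    labels <- c(labels, rep(ci, length(fs)))
  }
  images <- array(0, c(size[1L], size[2L], 3L, length(files)))
  for (i in seq_along(files)) {
    e <- tryCatch(EBImage::readImage(files[[i]]),
                  error = function(err)
                    stop("unreadable image: ", files[[i]], " (",
                         conditionMessage(err), ")", call. = FALSE))
    a <- as.array(e)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    a <- aperm(a, c(2L, 1L, 3L))                       # EBImage is x,y order
    if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE] # drop alpha
    images[, , , i] <- resize_image(pmin(pmax(a, 0), 1), size[1L], size[2L])
  }
  tnv2_imageset(images, labels, classes, split)
}

#' Write an image set as a directory-per-class tree
#'
#' Inverse of [read_image_folder()]; one PNG per image, named
#' `img_<index>.png` within its class directory.
#'
#' @param set a [tnv2_imageset].
#' @param root output directory (created if missing).
#' @export
write_image_folder <- function(set, root) {
  for (ci in seq_along(set$class_names))
    dir.create(file.path(root, set$class_names[ci]), recursive = TRUE,
               showWarnings = FALSE)
  n <- length(set)
  for (i in seq_len(n)) {
    a <- set$images[, , , i, drop = TRUE]
    e <- EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
    EBImage::writeImage(e, file.path(root, set$class_names[set$labels[i]],
                                     sprintf("img_%04d.png", i)))
  }
  invisible(root)
}

#' Stratified train/validation split
#'
#' Randomized per-class partition, reproducible under `seed`; the two outputs
#' are disjoint and exhaustive. The training fraction is rounded per class
#' with `round()`, matching an 80:20 split exactly when class sizes are
#' multiples of five.
#'
#' @param set a [tnv2_imageset].
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with elements `train` and `val`.
#' @export
split_train_val <- function(set, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr <- integer()
  for (ci in seq_along(set$class_names)) {
    idx <- which(set$labels == ci)
    if (length(idx) < 2L)
      stop(sprintf("class '%s' has fewer than 2 items",
                   set$class_names[ci]), call. = FALSE)
    ntr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
    tr <- c(tr, sample(idx, ntr))
  }
  tr <- sort(tr)
  va <- setdiff(seq_len(length(set)), tr)
  train <- subset_imageset(set, tr); train$split <- "train"
  val <- subset_imageset(set, va); val$split <- "val"
  hs <- attr(set, "hotspots")
  if (!is.null(hs)) {
    attr(train, "hotspots") <- hs[tr]
    attr(val, "hotspots") <- hs[va]
  }
  list(train = train, val = val)
}

# ---- synthetic plantar-pressure generator ----------------------------------

# foot-shaped mask on an s x s grid: forefoot + arch + heel ellipses
foot_mask <- function(s, jitter = c(0, 0)) {
  hh <- matrix(seq_len(s), s, s) / s
  ww <- matrix(seq_len(s), s, s, byrow = TRUE) / s
  hh <- hh - jitter[1L]; ww <- ww - jitter[2L]
  ell <- function(ch, cw, rh, rw)
    ((hh - ch) / rh)^2 + ((ww - cw) / rw)^2 <= 1
  ell(0.30, 0.52, 0.17, 0.20) |            # forefoot
    ell(0.55, 0.46, 0.20, 0.11) |          # arch (narrow)
    ell(0.78, 0.50, 0.13, 0.13)            # heel
}

# add amp * N((ch,cw), sigma^2) to pat, evaluated on a +/- 4 sigma window
gauss_stamp <- function(pat, ch, cw, sigma, amp) {
  s <- nrow(pat)
  r <- ceiling(4 * sigma)
  hs <- max(1L, floor(ch - r)):min(s, ceiling(ch + r))
  ws <- max(1L, floor(cw - r)):min(s, ceiling(cw + r))
  bh <- exp(-(hs - ch)^2 / (2 * sigma^2))
  bw <- exp(-(ws - cw)^2 / (2 * sigma^2))
  pat[hs, ws] <- pat[hs, ws] + amp * outer(bh, bw)
  pat
}

#' Generate synthetic plantar-pressure images
#'
#' Emulates weight-normalized pedobarograph frames with a foot-shaped support
#' region, a heel-to-toe center-of-pressure (COP) ridge, background noise,
#' and two loading regimes: the "osteoarthritis" class concentrates load in
#' 1-3 compact high-intensity hotspots (focal loading), the "control" class
#' spreads a comparable load over several broad low bumps (diffuse loading).
#' Every image's total mass is normalized to the same constant, emulating
#' body-weight normalization, so the classes differ in contrast, not energy.
#' Generation is a pure function of the arguments; the same seed yields
#' identical images. Hotspot centers and radii of the focal class are
#' attached as the `"hotspots"` attribute (one data.frame per image) for
#' localization checks.
#'
#' @param n_per_class images per class.
#' @param seed integer seed.
#' @param size square image side in pixels (default 224).
#' @param n_hotspots integer range of focal hotspots per image.
#' @param hotspot_sigma focal hotspot radius range, in pixels at `size` 224
#'   (scaled proportionally for other sizes).
#' @param hotspot_amp focal hotspot peak amplitude range (pattern units).
#' @param diffuse_sigma,diffuse_amp radius and amplitude ranges of the broad
#'   control-class bumps.
#' @param n_diffuse integer range of broad bumps per control image.
#' @param noise_sd additive Gaussian background noise (pattern units),
#'   applied inside the frame before normalization.
#' @param mass_frac normalized per-image total mass, as a fraction of the
#'   pixel count.
#' @return a [tnv2_imageset] with classes `c("control", "osteoarthritis")`
#'   (lexicographic order).
#' @export
generate_pressure_images <- function(n_per_class, seed = 1L, size = 224L,
                                     n_hotspots = c(1L, 3L),
                                     hotspot_sigma = c(4, 8),
                                     hotspot_amp = c(0.7, 1.0),
                                     diffuse_sigma = c(22, 34),
                                     diffuse_amp = c(0.12, 0.22),
                                     n_diffuse = c(4L, 7L),
                                     noise_sd = 0.02,
                                     mass_frac = 0.025) {
  stopifnot(n_per_class >= 1L, size >= 32L)
  scale <- size / 224
  if (max(hotspot_sigma) * scale > size / 4)
    stop("hotspot radius exceeds the foot mask", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  classes <- c("control", "osteoarthritis")   # diffuse, focal
  n <- 2L * n_per_class
  images <- array(0, c(size, size, 3L, n))
  labels <- integer(n)
  hotlist <- vector("list", n)
  mass <- mass_frac * size^2
  runifr <- function(r, k = 1L) stats::runif(k, r[1L], r[2L])
  sampr <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
  i <- 0L
  for (ci in 1:2) for (j in seq_len(n_per_class)) {
    i <- i + 1L
    labels[i] <- ci
    jit <- stats::runif(2L, -0.02, 0.02)
    mask <- foot_mask(size, jit)
    pat <- mask * 0.15
    # center-of-pressure ridge: heel -> forefoot polyline with lateral sway
    tpts <- seq(0, 1, length.out = 40L)
    ch <- (0.80 - 0.58 * tpts + jit[1L]) * size
    cw <- (0.50 + 0.06 * sin(tpts * pi * stats::runif(1L, 1.5, 2.5)) +
             jit[2L]) * size
    for (k in seq_along(tpts))
      pat <- gauss_stamp(pat, ch[k], cw[k], 2.2 * scale, 0.045)
    inside <- which(mask, arr.ind = TRUE)
    if (ci == 2L) {                           # focal / osteoarthritis-like
      nh <- sampr(n_hotspots)
      hs <- data.frame(h = numeric(nh), w = numeric(nh), sigma = numeric(nh))
      for (k in seq_len(nh)) {
        ctr <- inside[sample(nrow(inside), 1L), ]
        sg <- runifr(hotspot_sigma) * scale
        amp <- runifr(hotspot_amp)
        pat <- gauss_stamp(pat, ctr[1L], ctr[2L], sg, amp)
        hs[k, ] <- c(ctr[1L], ctr[2L], sg)
      }
      hotlist[[i]] <- hs
    } else {                                  # diffuse / control-like
      nd <- sampr(n_diffuse)
      for (k in seq_len(nd)) {
        ctr <- inside[sample(nrow(inside), 1L), ]
        pat <- gauss_stamp(pat, ctr[1L], ctr[2L],
                           runifr(diffuse_sigma) * scale, runifr(diffuse_amp))
      }
      hotlist[[i]] <- data.frame(h = numeric(0), w = numeric(0),
                                 sigma = numeric(0))
    }
    if (noise_sd > 0)
      pat <- pat + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
    pat[pat < 0] <- 0
    pat <- pat * (mass / sum(pat))            # body-weight normalization
    if (max(pat) > 1)                         # guard; defaults never reach it
      pat <- pat / max(pat)
    images[, , 1L, i] <- pat
    images[, , 2L, i] <- pat
    images[, , 3L, i] <- pat
  }
  set <- tnv2_imageset(images, labels, classes)
  attr(set, "hotspots") <- hotlist
  set
}
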