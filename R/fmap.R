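#' Feature maps
#'
#' Activations flowing between blocks are rank-3 tensors (height x width x
#' channels), batched over images. Internally a batch is stored as a dense
#' matrix with `n * h * w` rows (image slowest, then row, then column) and one
#' column per channel, so that every 1x1 convolution is a single BLAS matrix
#' product and every pooling window is a set of row gathers. `fmap` objects
#' carry the spatial geometry alongside the matrix.
#'
#' @param x numeric matrix with `n * h * w` rows and `channels` columns.
#' @param n,h,w batch size and spatial extents.
#' @return An object of class `"fmap"`.
#' @export
fmap <- function(x, n, h, w) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == n * h * w, n >= 1, h >= 1, w >= 1, ncol(x) >= 1)
  structure(list(x = x, n = as.integer(n), h = as.integer(h),
                 w = as.integer(w)), class = "fmap")
}

#' @export
print.fmap <- function(x, ...) {
  cat(sprintf("<fmap> %d x %dx%dx%d (n x HxWxC)\n", x$n, x$h, x$w, ncol(x$x)))
  invisible(x)
}

#' @export
dim.fmap <- function(x) c(x$n, x$h, x$w, ncol(x$x))

#' Convert image arrays to feature maps and back
#'
#' `as_fmap()` accepts a single image (`h x w x c` array) or a batch
#' (`h x w x c x n`). `fmap_to_array()` inverts it.
#'
#' @param a numeric array.
#' @return `as_fmap()`: an [fmap]; `fmap_to_array()`: an `h x w x c x n` array.
#' @export
as_fmap <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) { a <- array(a, c(d, 1L)); d <- dim(a) }
  if (length(d) == 3L) { a <- array(a, c(d, 1L)); d <- dim(a) }
  stopifnot(length(d) == 4L)
  # row order: image, then h, then w fastest -> permute to (w, h, n, c)
  m <- matrix(aperm(a, c(2L, 1L, 4L, 3L)), ncol = d[3L])
  fmap(m, n = d[4L], h = d[1L], w = d[2L])
}

#' @rdname as_fmap
#' @param fm an [fmap].
#' @export
fmap_to_array <- function(fm) {
  c_ <- ncol(fm$x)
  a <- array(fm$x, c(fm$w, fm$h, fm$n, c_))
  aperm(a, c(2L, 1L, 4L, 3L))
}

# ---- window index cache ----------------------------------------------------
# For a pooling/conv window (kh x kw, stride, pad) over an (n, h, w) batch,
# idx[r, k] is the source row feeding output row r through window slot k
# (slots in row-major order over the window), or the shared padding row.

.idx_cache <- new.env(parent = emptyenv())

window_index <- function(h, w, n, kh, kw, stride, pad) {
  key <- paste(h, w, n, kh, kw, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- (h + 2L * pad - kh) %/% stride + 1L
  ow <- (w + 2L * pad - kw) %/% stride + 1L
  stopifnot(oh >= 1L, ow >= 1L)
  oi <- rep(seq_len(oh), each = ow)          # output row coordinate
  oj <- rep(seq_len(ow), times = oh)         # output col coordinate
  top  <- (oi - 1L) * stride - pad           # 0-based
  left <- (oj - 1L) * stride - pad
  idx1 <- matrix(NA_integer_, oh * ow, kh * kw)
  k <- 0L
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    k <- k + 1L
    sh <- top + a; sw <- left + b            # 1-based source coords
    ok <- sh >= 1L & sh <= h & sw >= 1L & sw <= w
    v <- (sh - 1L) * w + sw
    v[!ok] <- NA_integer_
    idx1[, k] <- v
  }
  pad_row <- n * h * w + 1L
  if (n == 1L) {
    idx <- idx1
  } else {
    idx <- idx1[rep(seq_len(oh * ow), times = n), , drop = FALSE] +
      rep((seq_len(n) - 1L) * (h * w), each = oh * ow)
  }
  idx[is.na(idx)] <- pad_row
  out <- list(idx = idx, oh = oh, ow = ow, pad_row = pad_row)
  .idx_cache[[key]] <- out
  out
}
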