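# Internal raster helpers. Images are base-R numeric matrices (grayscale,
# rows = y, cols = x) or height x width x 3 arrays (RGB), intensities 0..255.
# Binary masks are integer matrices of {0, 1} with the same orientation.

#' @importFrom stats median quantile rnorm runif rpois var sd setNames predict
#' @importFrom utils head tail
NULL

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_gray <- function(x, arg = deparse(substitute(x))) {
  if (!is_gray_image(x)) stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg), call. = FALSE)
  invisible(x)
}

assert_rgb <- function(x, arg = deparse(substitute(x))) {
  if (!is_rgb_image(x)) stop(sprintf("`%s` must be a height x width x 3 numeric array (RGB image)", arg), call. = FALSE)
  invisible(x)
}

assert_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be a binary {0,1} matrix", arg), call. = FALSE)
  }
  invisible(x)
}

assert_odd_window <- function(w, arg = deparse(substitute(w))) {
  if (length(w) != 1L || w < 3L || w %% 2L == 0L) {
    stop(sprintf("`%s` must be an odd integer >= 3", arg), call. = FALSE)
  }
  invisible(as.integer(w))
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  m[ri, ci, drop = FALSE]
}

# Shift with replicate boundary: value at (i, j) becomes value at (i+di, j+dj),
# clamped to the image domain.
shift_replicate <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + di, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dj, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Box sums over a (2r+1)^2 window with replicate padding, via integral image.
box_sum <- function(m, r) {
  p <- pad_replicate(m, r)
  cs <- apply(p, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs))
  h <- nrow(m); w <- ncol(m); k <- 2L * r + 1L
  i1 <- seq_len(h); j1 <- seq_len(w)
  cs[i1 + k, j1 + k, drop = FALSE] - cs[i1, j1 + k, drop = FALSE] -
    cs[i1 + k, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}

# Offsets of a centred digital line structuring element of given length/angle.
line_offsets <- function(length, angle_deg) {
  half <- (length - 1) / 2
  t <- seq(-half, half, by = 1)
  th <- angle_deg * pi / 180
  off <- unique(cbind(round(-t * sin(th)), round(t * cos(th))))
  storage.mode(off) <- "integer"
  off
}

# Grayscale dilation/erosion with an arbitrary offset structuring element,
# replicate boundary handling.
gray_dilate <- function(m, offsets) {
  out <- shift_replicate(m, offsets[1, 1], offsets[1, 2])
  for (k in seq_len(nrow(offsets))[-1]) {
    out <- pmax(out, shift_replicate(m, offsets[k, 1], offsets[k, 2]))
  }
  out
}

gray_erode <- function(m, offsets) {
  out <- shift_replicate(m, offsets[1, 1], offsets[1, 2])
  for (k in seq_len(nrow(offsets))[-1]) {
    out <- pmin(out, shift_replicate(m, offsets[k, 1], offsets[k, 2]))
  }
  out
}

gray_close <- function(m, offsets) gray_erode(gray_dilate(m, offsets), -offsets)

# Bilinear sampling of matrix m at fractional (row, col) positions.
bilinear_sample <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(rows, 1), h)
  cols <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(rows), h - 1L); c0 <- pmin(floor(cols), w - 1L)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Even-odd scan fill of a closed polygon (vertices as (row, col) in pixel
# units) onto a h x w binary mask. Pixel centres at integer coordinates.
fill_polygon <- function(vr, vc, h, w) {
  mask <- matrix(0L, h, w)
  n <- length(vr)
  nxt <- c(seq_len(n)[-1], 1L)
  for (row in seq_len(h)) {
    y <- row
    y1 <- vr; y2 <- vr[nxt]
    crosses <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crosses)) next
    xs <- vc[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (vc[nxt][crosses] - vc[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1])
      if (b >= a) {
        a <- max(a, 1L); b <- min(b, w)
        if (b >= a) mask[row, a:b] <- 1L
      }
    }
  }
  mask
}

#' Read an image file as an 8-bit raster
#'
#' Reads a PNG file into the package's raster convention: a `height x width`
#' matrix (grayscale) or `height x width x 3` array (RGB) of intensities in
#' 0..255.
#'
#' @param path path to a PNG file.
#' @return numeric matrix or array with intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE] else a <- a[, , 1]
  }
  round(a * 255)
}

#' Write an 8-bit raster to a PNG file
#'
#' @param image matrix or `h x w x 3` array with intensities in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp255(image) / 255, path)
  invisible(path)
}

#' Read a binary lesion mask from a PNG file
#'
#' Any pixel above half intensity is treated as foreground.
#'
#' @param path path to a single-channel (or RGB) PNG mask.
#' @return integer matrix of `{0, 1}`.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- (a > 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write a binary mask as a {0, 255} PNG
#'
#' @param mask integer matrix of `{0, 1}`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
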