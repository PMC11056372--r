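# Gray-level co-occurrence matrix (GLCM) and the 20 second-order texture
# statistics (Haralick 1973; Soh & Tsatsoulis 1999; Clausi 2002 definitions).

#' Compute a normalized, symmetrized GLCM
#'
#' Quantizes intensities by linear binning of `range` into `levels` bins and
#' counts co-occurring gray-level pairs for pixel pairs separated by `offset`
#' with both pixels inside `mask`. The count matrix is symmetrized (added to
#' its transpose) and normalized to sum 1.
#'
#' @param image grayscale matrix.
#' @param mask binary matrix restricting the pairs, or `NULL` for the full
#'   image.
#' @param offset integer `(dx, dy)` displacement: `dx` columns to the right,
#'   `dy` rows down.
#' @param levels number of quantization bins (>= 2).
#' @param range intensity range mapped onto the bins (default full 8-bit).
#' @return a `glcm` object: `levels x levels` matrix of probabilities with
#'   `offset` and `levels` attributes.
#' @export
compute_glcm <- function(image, mask = NULL, offset = c(1L, 0L), levels = 8L,
                         range = c(0, 255)) {
  assert_gray(image)
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  if (all(offset == 0)) stop("`offset` must be nonzero", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (is.null(mask)) mask <- matrix(1L, h, w)
  assert_mask(mask)
  if (!any(mask == 1L)) stop("`mask` is empty", call. = FALSE)
  q <- pmin(pmax(floor((image - range[1]) / (range[2] - range[1] + 1) * levels) + 1L, 1L), levels)
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  r1 <- max(1L, 1L - dy):min(h, h - dy)
  c1 <- max(1L, 1L - dx):min(w, w - dx)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] == 1L & mask[r1 + dy, c1 + dx, drop = FALSE] == 1L
  ai <- a[ok]; bi <- b[ok]
  counts <- matrix(0, levels, levels)
  if (length(ai) > 0) {
    tab <- tabulate((bi - 1L) * levels + ai, nbins = levels * levels)
    counts <- matrix(tab, levels, levels)
  }
  counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) {
    stop("`mask` contains no co-occurring pixel pairs for this offset", call. = FALSE)
  }
  p <- counts / total
  structure(p, class = c("glcm", "matrix"), offset = c(dx, dy), levels = levels)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 20 GLCM texture statistics
#'
#' Computes, from a normalized GLCM `p(i, j)`: autocorrelation, contrast,
#' correlation, cluster prominence, cluster shade, dissimilarity, energy,
#' entropy, homogeneity, maximum probability, sum of squares (variance about
#' the GLCM mean), sum average, sum variance, sum entropy, difference
#' variance, difference entropy, the two information measures of correlation,
#' inverse difference normalized (IDN) and inverse difference moment
#' normalized (IDMN). Logs are base 2; sum variance is centred on the sum
#' average; for degenerate (zero-variance) matrices correlation and the first
#' information measure are defined as 0.
#'
#' @param glcm a normalized `glcm` matrix (entries sum to 1).
#' @return named numeric vector of length 20.
#' @export
glcm_statistics <- function(glcm) {
  p <- unclass(glcm)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("`glcm` must be a normalized co-occurrence matrix (entries >= 0 summing to 1)",
         call. = FALSE)
  }
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px)); sy <- sqrt(sum((seq_len(n) - muy)^2 * py))

  # p_{x+y}(k), k = 2..2n and p_{x-y}(k), k = 0..n-1
  psum <- vapply(2:(2 * n), function(k) sum(p[i + j == k]), numeric(1))
  ks <- 2:(2 * n)
  pdiff <- vapply(0:(n - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kd <- 0:(n - 1)

  autocorrelation <- sum(i * j * p)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx > 0 && sy > 0) (autocorrelation - mux * muy) / (sx * sy) else 0
  cluster_prominence <- sum((i + j - mux - muy)^4 * p)
  cluster_shade <- sum((i + j - mux - muy)^3 * p)
  dissimilarity <- sum(abs(i - j) * p)
  energy <- sum(p^2)
  entropy <- entropy_bits(p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  maximum_probability <- max(p)
  mu <- sum(i * p)  # GLCM mean (equals mux for a symmetric matrix)
  sum_of_squares <- sum((i - mu)^2 * p)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- entropy_bits(psum)
  diff_mean <- sum(kd * pdiff)
  difference_variance <- sum((kd - diff_mean)^2 * pdiff)
  difference_entropy <- entropy_bits(pdiff)

  hx <- entropy_bits(px); hy <- entropy_bits(py)
  pxy <- outer(px, py)
  pos <- pxy > 0 & p > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- entropy_bits(pxy)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * log(2) * (hxy2 - entropy)), 0))

  inverse_difference_normalized <- sum(p / (1 + abs(i - j) / n))
  inverse_difference_moment_normalized <- sum(p / (1 + (i - j)^2 / n^2))

  c(autocorrelation = autocorrelation, contrast = contrast,
    correlation = correlation, cluster_prominence = cluster_prominence,
    cluster_shade = cluster_shade, dissimilarity = dissimilarity,
    energy = energy, entropy = entropy, homogeneity = homogeneity,
    maximum_probability = maximum_probability, sum_of_squares = sum_of_squares,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    inverse_difference_normalized = inverse_difference_normalized,
    inverse_difference_moment_normalized = inverse_difference_moment_normalized)
}
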