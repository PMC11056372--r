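# Pre-processing chain: DullRazor-style hair removal, grayscale conversion,
# contrast enhancement, and the median / Gaussian / Lee smoothing bank.

#' Pre-processing configuration
#'
#' Free parameters of the pre-processing chain. All windows are odd pixel
#' counts; `contrast_clip` is the tail fraction clipped by the histogram
#' stretch; `apply_negative` controls whether the final smoothed image is
#' negated (max-minus-pixel) before segmentation.
#'
#' @param hair_kernel_length length (px) of the line structuring elements used
#'   for hair detection.
#' @param hair_threshold minimum closing-minus-original response (gray levels)
#'   for a pixel to be considered hair.
#' @param median_window odd window (px) of the median filter.
#' @param gaussian_sigma standard deviation (px) of the Gaussian filter.
#' @param lee_window odd window (px) of the Lee filter.
#' @param contrast_clip clipped tail fraction in `(0, 1]` for contrast
#'   enhancement.
#' @param apply_negative logical; negate the final image.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(hair_kernel_length = 9L, hair_threshold = 10,
                              median_window = 3L, gaussian_sigma = 1,
                              lee_window = 5L, contrast_clip = 0.01,
                              apply_negative = FALSE) {
  assert_odd_window(median_window)
  assert_odd_window(lee_window)
  if (gaussian_sigma <= 0) stop("`gaussian_sigma` must be > 0", call. = FALSE)
  if (contrast_clip <= 0 || contrast_clip > 1) stop("`contrast_clip` must be in (0, 1]", call. = FALSE)
  if (hair_kernel_length < 3) stop("`hair_kernel_length` must be >= 3", call. = FALSE)
  structure(list(hair_kernel_length = as.integer(hair_kernel_length),
                 hair_threshold = hair_threshold,
                 median_window = as.integer(median_window),
                 gaussian_sigma = gaussian_sigma,
                 lee_window = as.integer(lee_window),
                 contrast_clip = contrast_clip,
                 apply_negative = isTRUE(apply_negative)),
            class = "preprocess_config")
}

# Detect hair pixels on a grayscale detection channel: generalized closing
# with line structuring elements at 0/45/90/135 degrees. Candidate pixels must
# exceed the 90th percentile of the response by at least `threshold` gray
# levels (so smooth skin yields nothing while high-contrast hairs stand out);
# candidate components must be long (second-moment length) and thin (emptied
# by a 5 px disc erosion) to count as hair.
detect_hair <- function(gray, kernel_length, threshold) {
  angles <- c(0, 45, 90, 135)
  resp <- vector("list", 4L)
  for (k in 1:4) {
    off <- line_offsets(kernel_length, angles[k])
    resp[[k]] <- gray_close(gray, off) - gray
  }
  rmax <- Reduce(pmax, resp)
  thr <- max(threshold, quantile(rmax, 0.90) + threshold)
  cand <- (rmax > thr) * 1L
  storage.mode(cand) <- "integer"
  if (!any(cand == 1L)) {
    return(list(mask = cand, orientation = matrix(0L, nrow(gray), ncol(gray))))
  }
  lab <- EBImage::bwlabel(cand)
  eroded <- EBImage::erode(cand, EBImage::makeBrush(5L, "disc"))
  groups <- split(seq_along(lab)[lab > 0], lab[lab > 0])
  keep <- integer(0)
  h <- nrow(gray)
  for (id in names(groups)) {
    lin <- groups[[id]]
    n <- length(lin)
    if (n < 2L * kernel_length) next
    if (sum(eroded[lin]) / n >= 0.1) next  # too thick to be hair
    idx <- cbind((lin - 1L) %% h + 1L, (lin - 1L) %/% h + 1L)
    cv <- stats::cov(idx) * (n - 1) / n
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (4 * sqrt(max(ev[1], 0)) >= 1.5 * kernel_length) keep <- c(keep, as.integer(id))
  }
  mask <- (matrix(lab, nrow(gray), ncol(gray)) %in% keep) * 1L
  dim(mask) <- dim(gray)
  # grow by one pixel to cover anti-aliased stroke borders
  mask <- (box_sum(mask, 1L) > 0) * 1L
  storage.mode(mask) <- "integer"
  ori <- max.col(cbind(as.vector(resp[[1]]), as.vector(resp[[2]]),
                       as.vector(resp[[3]]), as.vector(resp[[4]])),
                 ties.method = "first")
  dim(ori) <- dim(gray)
  list(mask = mask, orientation = ori)
}

# Replace hair pixels by linear interpolation between the nearest non-hair
# pixels along the direction perpendicular to the detected hair orientation.
inpaint_channel <- function(ch, mask, orientation, max_step) {
  dirs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))  # normals to 0/45/90/135
  h <- nrow(ch); w <- ncol(ch)
  out <- ch
  hair_idx <- which(mask == 1L)
  if (length(hair_idx) == 0) return(out)
  rows0 <- ((hair_idx - 1L) %% h) + 1L
  cols0 <- ((hair_idx - 1L) %/% h) + 1L
  oris <- orientation[hair_idx]
  oris[oris < 1L | oris > 4L] <- 1L
  val <- numeric(length(hair_idx)); wt <- numeric(length(hair_idx))
  for (o in 1:4) {
    sel <- which(oris == o)
    if (length(sel) == 0) next
    d <- dirs[[o]]
    for (sgn in c(1L, -1L)) {
      pend <- seq_along(sel)
      v <- rep(NA_real_, length(sel)); dist <- rep(NA_real_, length(sel))
      for (s in seq_len(max_step)) {
        if (length(pend) == 0) break
        rr <- rows0[sel[pend]] + sgn * s * d[1]
        cc <- cols0[sel[pend]] + sgn * s * d[2]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        found <- logical(length(pend))
        if (any(ok)) {
          lin <- (cc[ok] - 1L) * h + rr[ok]
          nonhair <- mask[lin] == 0L
          found[ok] <- nonhair
          v[pend[which(ok)[nonhair]]] <- ch[lin[nonhair]]
          dist[pend[which(ok)[nonhair]]] <- s
        }
        pend <- pend[ok & !found]
      }
      got <- !is.na(v)
      val[sel[got]] <- val[sel[got]] + v[got] / dist[got]
      wt[sel[got]] <- wt[sel[got]] + 1 / dist[got]
    }
  }
  fixed <- wt > 0
  out[hair_idx[fixed]] <- round(val[fixed] / wt[fixed])
  # fallback for pixels with no clear line: iterative non-hair neighbour mean
  rem <- hair_idx[!fixed]
  guard <- 0L
  while (length(rem) > 0 && guard < 10L) {
    guard <- guard + 1L
    known <- matrix(1, h, w); known[rem] <- 0
    num <- box_sum(out * known, 1L); den <- box_sum(known, 1L)
    solv <- rem[den[rem] > 0]
    out[solv] <- round(num[solv] / den[solv])
    rem <- setdiff(rem, solv)
  }
  clamp255(out)
}

#' Remove hair artifacts (DullRazor-style)
#'
#' Detects dark curvilinear structures by grayscale morphological closing with
#' line structuring elements at 0, 45, 90 and 135 degrees on the luminance
#' channel. Pixels whose closing-minus-original response exceeds both
#' `threshold` and an adaptive noise floor, and that belong to long thin
#' connected components, are treated as hair and replaced per channel by
#' linear interpolation between the nearest non-hair pixels along the line
#' normal. Hairless input passes through with bounded change.
#'
#' @param image RGB array (`h x w x 3`, 0..255).
#' @param kernel_length line structuring-element length in px (>= 3).
#' @param threshold minimum hair response in gray levels.
#' @return RGB array of the same shape.
#' @export
remove_hair <- function(image, kernel_length = 9L, threshold = 10) {
  assert_rgb(image)
  if (kernel_length < 3) stop("`kernel_length` must be >= 3", call. = FALSE)
  gray <- to_grayscale(image)
  det <- detect_hair(gray, as.integer(kernel_length), threshold)
  if (!any(det$mask == 1L)) return(image)
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- inpaint_channel(image[, , ch], det$mask, det$orientation,
                                   max_step = as.integer(kernel_length))
  }
  attr(out, "hair_mask") <- det$mask
  out
}

#' Photographic negative of a grayscale image
#'
#' Each output pixel is the image maximum minus the input pixel, so the
#' brightest pixel maps to zero.
#'
#' @param image grayscale matrix.
#' @return grayscale matrix.
#' @export
img_negative <- function(image) {
  assert_gray(image)
  if (length(image) == 0) stop("empty image", call. = FALSE)
  max(image) - image
}

#' Convert RGB to 8-bit grayscale luminance
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded to
#' 8-bit.
#'
#' @param image RGB array (`h x w x 3`, 0..255).
#' @return grayscale matrix.
#' @export
to_grayscale <- function(image) {
  assert_rgb(image)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Median filter with replicate-border padding
#'
#' @param image grayscale matrix.
#' @param window odd window size in px.
#' @return grayscale matrix.
#' @export
median_filter <- function(image, window = 3L) {
  assert_gray(image)
  window <- assert_odd_window(window)
  r <- (window - 1L) %/% 2L
  p <- pad_replicate(image, r) / 255
  f <- EBImage::medianFilter(p, r)
  h <- nrow(image); w <- ncol(image)
  round(f[(r + 1):(r + h), (r + 1):(r + w), drop = FALSE] * 255)
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing filter
#'
#' Separable convolution with a normalized Gaussian kernel (radius 3 sigma),
#' replicate-border padding. Constant images are preserved.
#'
#' @param image grayscale matrix.
#' @param sigma kernel standard deviation in px (> 0).
#' @param round logical; round the result to 8-bit (default).
#' @return grayscale matrix.
#' @export
gaussian_filter <- function(image, sigma = 1, round = TRUE) {
  assert_gray(image)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(image, i - r - 1L, 0L)
  out2 <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_replicate(out, 0L, i - r - 1L)
  if (round) round(out2) else out2
}

#' Lee adaptive local-statistics filter
#'
#' `out = mean + k * (in - mean)` with `k = var / (var + noise_var)` computed
#' over the local window; the noise variance is estimated as the mean of the
#' local variances. Smooths homogeneous regions while leaving strong edges
#' (where local variance dominates) nearly untouched.
#'
#' @param image grayscale matrix.
#' @param window odd window size in px.
#' @return grayscale matrix.
#' @export
lee_filter <- function(image, window = 5L) {
  assert_gray(image)
  window <- assert_odd_window(window)
  r <- (window - 1L) %/% 2L
  n <- window^2
  mu <- box_sum(image, r) / n
  v <- pmax(box_sum(image^2, r) / n - mu^2, 0)
  noise_var <- mean(v)
  k <- ifelse(v + noise_var > 0, v / (v + noise_var), 0)
  round(mu + k * (image - mu))
}

#' Contrast enhancement by clipped histogram stretch
#'
#' Linearly rescales intensities so that the `clip/2` and `1 - clip/2`
#' quantiles map to 0 and 255, clipping the tails. Monotone in the input
#' ordering; a constant image is returned unchanged.
#'
#' @param image grayscale matrix.
#' @param clip clipped tail fraction in `(0, 1]`.
#' @return grayscale matrix.
#' @export
enhance_contrast <- function(image, clip = 0.01) {
  assert_gray(image)
  if (clip <= 0 || clip > 1) stop("`clip` must be in (0, 1]", call. = FALSE)
  lo <- quantile(image, clip / 2, names = FALSE)
  hi <- quantile(image, 1 - clip / 2, names = FALSE)
  if (hi <= lo) return(image)
  round(clamp255((image - lo) / (hi - lo) * 255))
}

#' Full pre-processing pipeline
#'
#' Applies, in order: hair removal, grayscale conversion, contrast
#' enhancement, median filter, Gaussian filter, Lee filter, and (optionally)
#' the photographic negative. Stage timings are attached as the `"stages"`
#' attribute (a tibble).
#'
#' @param image RGB array (`h x w x 3`, 0..255).
#' @param config a [preprocess_config()].
#' @return smoothed grayscale matrix with a `"stages"` attribute.
#' @export
preprocess_pipeline <- function(image, config = preprocess_config()) {
  assert_rgb(image)
  stopifnot(inherits(config, "preprocess_config"))
  stages <- list(
    remove_hair = function(x) remove_hair(x, config$hair_kernel_length, config$hair_threshold),
    to_grayscale = to_grayscale,
    enhance_contrast = function(x) enhance_contrast(x, config$contrast_clip),
    median_filter = function(x) median_filter(x, config$median_window),
    gaussian_filter = function(x) gaussian_filter(x, config$gaussian_sigma),
    lee_filter = function(x) lee_filter(x, config$lee_window)
  )
  if (config$apply_negative) stages$negative <- img_negative
  out <- image
  log <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(stages[[i]](out), error = function(e) {
      stop(sprintf("pre-processing stage `%s` failed: %s", names(stages)[i],
                   conditionMessage(e)), call. = FALSE)
    })
    log[[i]] <- tibble::tibble(stage = names(stages)[i],
                               elapsed_s = proc.time()[["elapsed"]] - t0)
  }
  attributes(out) <- attributes(out)[c("dim")]
  attr(out, "stages") <- dplyr::bind_rows(log)
  out
}
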