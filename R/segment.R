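# Lesion segmentation: adaptive snake (active contour) and seeded region
# growing, with morphological cleanup and pixel-accuracy scoring.

#' Adaptive-snake parameters
#'
#' @param init_margin fraction of the image size left as background margin
#'   around the initial rectangular contour, in `(0, 0.5)`.
#' @param alpha elasticity weight of the internal energy (penalizes stretch).
#' @param beta rigidity weight of the internal energy (penalizes bending).
#' @param gamma iteration step size.
#' @param max_iterations iteration cap.
#' @param convergence_tol mean vertex displacement (px) below which the snake
#'   is considered converged.
#' @param n_points number of contour vertices.
#' @param edge_sigma Gaussian scale (px) for the edge map.
#' @param force_sigma Gaussian scale (px) used to diffuse the edge map so the
#'   gradient force has a wider capture range.
#' @param edge_weight weight of the image-gradient (edge attraction) force.
#' @param balloon_weight weight of the inward pressure force that shrinks the
#'   contour across homogeneous regions.
#' @param balloon_gate edge-map level (0..1) at which the pressure force is
#'   fully suppressed, so the contour stops at boundaries.
#' @param resample_every contour is resampled to equal arc length every this
#'   many iterations.
#' @return a `snake_params` list.
#' @export
snake_params <- function(init_margin = 0.25, alpha = 0.1, beta = 1.0,
                         gamma = 1.0, max_iterations = 250L,
                         convergence_tol = 0.1, n_points = 120L,
                         edge_sigma = 2, force_sigma = 4, edge_weight = 2,
                         balloon_weight = 0.6, balloon_gate = 0.5,
                         resample_every = 10L) {
  if (init_margin <= 0 || init_margin >= 0.5) stop("`init_margin` must be in (0, 0.5)", call. = FALSE)
  stopifnot(alpha > 0, beta > 0, gamma > 0, max_iterations >= 0,
            convergence_tol > 0, n_points >= 8)
  structure(as.list(environment()), class = "snake_params")
}

#' Region-growing parameters
#'
#' @param seed `(row, col)` seed pixel, or `NULL` to start from the centroid
#'   of the darkest smoothed region (lesions are dark).
#' @param intensity_tolerance maximum absolute difference (gray levels)
#'   between a candidate pixel and the running region mean.
#' @param connectivity 4 or 8.
#' @param open_radius,close_radius disc radii (px) for the morphological
#'   cleanup applied after growth.
#' @return a `region_grow_params` list.
#' @export
region_grow_params <- function(seed = NULL, intensity_tolerance = 30,
                               connectivity = 8L, open_radius = 2L,
                               close_radius = 4L) {
  if (intensity_tolerance < 0) stop("`intensity_tolerance` must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(seed = seed, intensity_tolerance = intensity_tolerance,
                 connectivity = as.integer(connectivity),
                 open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius)),
            class = "region_grow_params")
}

#' Rectangular initial mask for the snake
#'
#' Ones in a centred rectangle leaving a `margin` fraction of zeros on every
#' side.
#'
#' @param height,width mask size.
#' @param margin background margin fraction in `(0, 0.5)`.
#' @return binary matrix.
#' @export
make_init_mask <- function(height, width, margin = 0.25) {
  if (margin <= 0 || margin >= 0.5) stop("`margin` must be in (0, 0.5)", call. = FALSE)
  mh <- floor(margin * height); mw <- floor(margin * width)
  m <- matrix(0L, height, width)
  m[(mh + 1):(height - mh), (mw + 1):(width - mw)] <- 1L
  m
}

# Resample a closed polygon to n equally spaced vertices along arc length.
resample_contour <- function(P, n) {
  Pc <- rbind(P, P[1, ])
  seg <- sqrt(rowSums(diff(Pc)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(P[rep(1, n), , drop = FALSE])
  tq <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  r <- stats::approx(s, Pc[, 1], xout = tq, ties = "ordered")$y
  c_ <- stats::approx(s, Pc[, 2], xout = tq, ties = "ordered")$y
  cbind(r, c_)
}

# Cyclic pentadiagonal internal-energy system matrix inverse.
snake_system_inverse <- function(n, alpha, beta, gamma) {
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, idx(i - 1)] <- A[i, idx(i + 1)] <- -alpha - 4 * beta
    A[i, idx(i - 2)] <- A[i, idx(i + 2)] <- beta
    A[i, i] <- 2 * alpha + 6 * beta
  }
  solve(diag(n) + gamma * A)
}

#' Adaptive snake (active contour) segmentation
#'
#' Evolves a closed contour initialized on the rectangle of
#' [make_init_mask()] by semi-implicit gradient descent on internal
#' (elasticity + rigidity) plus external energy. The external force combines
#' the gradient of a Gaussian-diffused edge map (attraction to lesion
#' boundaries) with an inward pressure that is suppressed where edge response
#' is strong, giving the contour a capture range across smooth skin. Iteration
#' stops at `max_iterations` or when the mean vertex displacement falls below
#' `convergence_tol`. The filled final contour is returned as a mask;
#' convergence status, iteration count and the area trace are attached in the
#' `"snake"` attribute (non-convergence is reported there, not an error).
#'
#' @param image preprocessed (smooth) grayscale matrix.
#' @param params a [snake_params()].
#' @param init_contour optional `n x 2` matrix of `(row, col)` vertices of a
#'   closed initial contour; overrides the rectangular initialization.
#' @return binary mask with a `"snake"` metadata attribute.
#' @export
adaptive_snake <- function(image, params = snake_params(), init_contour = NULL) {
  assert_gray(image)
  stopifnot(inherits(params, "snake_params"))
  h <- nrow(image); w <- ncol(image)
  if (params$max_iterations == 0L) {
    init <- if (is.null(init_contour)) {
      make_init_mask(h, w, params$init_margin)
    } else {
      fill_polygon(init_contour[, 1], init_contour[, 2], h, w)
    }
    attr(init, "snake") <- list(converged = TRUE, iterations = 0L,
                                area_trace = sum(init))
    return(init)
  }
  # edge map and diffused force field
  sm <- gaussian_filter(image, params$edge_sigma, round = FALSE)
  gx <- (shift_replicate(sm, 0L, 1L) - shift_replicate(sm, 0L, -1L)) / 2
  gy <- (shift_replicate(sm, 1L, 0L) - shift_replicate(sm, -1L, 0L)) / 2
  E <- sqrt(gx^2 + gy^2)
  if (max(E) > 0) E <- E / max(E)
  Eb <- gaussian_filter(E, params$force_sigma, round = FALSE)
  Fr <- (shift_replicate(Eb, 1L, 0L) - shift_replicate(Eb, -1L, 0L)) / 2
  Fc <- (shift_replicate(Eb, 0L, 1L) - shift_replicate(Eb, 0L, -1L)) / 2
  fmax <- max(sqrt(Fr^2 + Fc^2))
  if (fmax > 0) { Fr <- Fr / fmax; Fc <- Fc / fmax }

  if (is.null(init_contour)) {
    mh <- floor(params$init_margin * h); mw <- floor(params$init_margin * w)
    init_contour <- cbind(
      c(seq(mh + 1, h - mh, length.out = 30), rep(h - mh, 30),
        seq(h - mh, mh + 1, length.out = 30), rep(mh + 1, 30)),
      c(rep(mw + 1, 30), seq(mw + 1, w - mw, length.out = 30),
        rep(w - mw, 30), seq(w - mw, mw + 1, length.out = 30)))
  }
  P <- resample_contour(init_contour, params$n_points)
  Minv <- snake_system_inverse(params$n_points, params$alpha, params$beta, params$gamma)

  n <- params$n_points
  area_trace <- numeric(0)
  converged <- FALSE
  iterations <- params$max_iterations
  for (it in seq_len(params$max_iterations)) {
    er <- bilinear_sample(E, P[, 1], P[, 2])
    fr <- bilinear_sample(Fr, P[, 1], P[, 2])
    fc <- bilinear_sample(Fc, P[, 1], P[, 2])
    # inward normal from the tangent, oriented toward the centroid
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    tr <- P[nxt, 1] - P[prv, 1]; tc <- P[nxt, 2] - P[prv, 2]
    tl <- pmax(sqrt(tr^2 + tc^2), 1e-9)
    nr <- -tc / tl; nc <- tr / tl
    ctr <- colMeans(P)
    inward <- sign(nr * (ctr[1] - P[, 1]) + nc * (ctr[2] - P[, 2]))
    nr <- nr * inward; nc <- nc * inward
    gate <- pmax(0, 1 - er / params$balloon_gate)
    fr_tot <- params$edge_weight * fr + params$balloon_weight * gate * nr
    fc_tot <- params$edge_weight * fc + params$balloon_weight * gate * nc
    Pn <- Minv %*% (P + params$gamma * cbind(fr_tot, fc_tot))
    Pn[, 1] <- pmin(pmax(Pn[, 1], 1), h)
    Pn[, 2] <- pmin(pmax(Pn[, 2], 1), w)
    disp <- mean(sqrt(rowSums((Pn - P)^2)))
    P <- Pn
    if (it %% params$resample_every == 0L) {
      P <- resample_contour(P, n)
      area_trace <- c(area_trace, polygon_area(P))
    }
    if (disp < params$convergence_tol) { converged <- TRUE; iterations <- it; break }
  }
  mask <- fill_polygon(P[, 1], P[, 2], h, w)
  # a self-intersecting contour can rasterize to several blobs; keep the
  # dominant one and fill interior holes
  if (any(mask == 1L)) mask <- morphological_cleanup(mask, 0L, 0L)
  attr(mask, "snake") <- list(converged = converged, iterations = iterations,
                              area_trace = area_trace, contour = P)
  mask
}

polygon_area <- function(P) {
  n <- nrow(P); nxt <- c(2:n, 1)
  abs(sum(P[, 2] * P[nxt, 1] - P[nxt, 2] * P[, 1])) / 2
}

#' Default region-growing seed: centroid of the darkest smoothed region
#'
#' Smooths the image (Gaussian, sigma 3), thresholds the darkest decile,
#' and returns the centroid of the largest connected component.
#'
#' @param image grayscale matrix.
#' @return integer `(row, col)`.
#' @export
default_seed <- function(image) {
  assert_gray(image)
  sm <- gaussian_filter(image, 3)
  dark <- (sm <= quantile(sm, 0.1)) * 1L
  storage.mode(dark) <- "integer"
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  as.integer(round(colMeans(idx)))
}

#' Seeded region growing segmentation
#'
#' Breadth-first growth from the seed pixel: at each step, unvisited
#' neighbours of the current frontier join the region when their intensity is
#' within `intensity_tolerance` of the running region mean (updated after each
#' frontier batch; each pixel is examined once, when first reached). Growth
#' runs to fixpoint; morphological opening/closing cleanup is then applied
#' unless `cleanup = FALSE`.
#'
#' @param image grayscale matrix.
#' @param params a [region_grow_params()].
#' @param cleanup logical; apply [morphological_cleanup()] afterwards.
#' @return binary mask.
#' @export
region_growing <- function(image, params = region_grow_params(), cleanup = TRUE) {
  assert_gray(image)
  stopifnot(inherits(params, "region_grow_params"))
  h <- nrow(image); w <- ncol(image)
  seed <- if (is.null(params$seed)) default_seed(image) else as.integer(params$seed)
  if (seed[1] < 1 || seed[1] > h || seed[2] < 1 || seed[2] > w) {
    stop("seed lies outside the image", call. = FALSE)
  }
  offs <- if (params$connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  visited <- matrix(FALSE, h, w)
  inreg <- matrix(FALSE, h, w)
  visited[seed[1], seed[2]] <- TRUE
  inreg[seed[1], seed[2]] <- TRUE
  rsum <- image[seed[1], seed[2]]; rn <- 1L
  fr_r <- seed[1]; fr_c <- seed[2]
  while (length(fr_r) > 0) {
    nr <- rep(fr_r, nrow(offs)) + rep(offs[, 1], each = length(fr_r))
    nc <- rep(fr_c, nrow(offs)) + rep(offs[, 2], each = length(fr_c))
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nr <- nr[ok]; nc <- nc[ok]
    lin <- (nc - 1L) * h + nr
    keep <- !duplicated(lin) & !visited[lin]
    lin <- lin[keep]; nr <- nr[keep]; nc <- nc[keep]
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    mu <- rsum / rn
    acc <- abs(image[lin] - mu) <= params$intensity_tolerance
    lin <- lin[acc]
    if (length(lin) == 0) break
    inreg[lin] <- TRUE
    rsum <- rsum + sum(image[lin]); rn <- rn + length(lin)
    fr_r <- nr[acc]; fr_c <- nc[acc]
  }
  mask <- inreg * 1L
  storage.mode(mask) <- "integer"
  if (cleanup) mask <- morphological_cleanup(mask, params$open_radius, params$close_radius)
  mask
}

#' Morphological mask cleanup
#'
#' Binary opening then closing with disc structuring elements, followed by
#' keeping only the largest connected component and filling interior holes.
#'
#' @param mask binary matrix.
#' @param open_radius,close_radius disc radii in px (0 skips the operation).
#' @return binary matrix.
#' @export
morphological_cleanup <- function(mask, open_radius = 2L, close_radius = 4L) {
  assert_mask(mask)
  if (open_radius < 0 || close_radius < 0) stop("radii must be >= 0", call. = FALSE)
  if (!any(mask == 1L)) return(mask)
  m <- mask
  if (open_radius > 0) m <- EBImage::opening(m, EBImage::makeBrush(2L * open_radius + 1L, "disc"))
  if (close_radius > 0) m <- EBImage::closing(m, EBImage::makeBrush(2L * close_radius + 1L, "disc"))
  m <- matrix(as.integer(m > 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  m <- (lab == which.max(sizes)) * 1L
  m <- EBImage::fillHull(m)
  m <- matrix(as.integer(m > 0), nrow(mask), ncol(mask))
  m
}

#' Pixel-wise segmentation accuracy with Dice and Jaccard
#'
#' Accuracy is `(TP + TN) / total` over all pixels; Dice and Jaccard score the
#' overlap of the foreground masks.
#'
#' @param predicted,truth binary masks of the same size.
#' @return one-row tibble with `accuracy`, `dice`, `jaccard` and the pixel
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
segmentation_accuracy <- function(predicted, truth) {
  assert_mask(predicted); assert_mask(truth)
  if (!all(dim(predicted) == dim(truth))) stop("mask dimensions differ", call. = FALSE)
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
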