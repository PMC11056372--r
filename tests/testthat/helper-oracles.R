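# Independent brute-force oracles and small fixture builders used across the
# suite. Every oracle is a direct, loop-based transcription of the defining
# computation, kept deliberately separate from the package's vectorized code
# paths.

# Binary disc mask of radius r centred in an n x n grid.
make_disc <- function(r, n = 2 * r + 21) {
  cx <- (n + 1) / 2
  m <- (outer(seq_len(n), seq_len(n),
              function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)) * 1L
  storage.mode(m) <- "integer"
  m
}

# Per-pixel inside-test rasterization of a perturbed ellipse (independent of
# rasterize_lesion's vectorized path).
oracle_rasterize <- function(spec, height, width) {
  m <- matrix(0L, height, width)
  th <- -spec$rotation * pi / 180
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      dr <- i - spec$center[1]; dc <- j - spec$center[2]
      u <- dr * cos(th) - dc * sin(th)
      v <- dr * sin(th) + dc * cos(th)
      rho <- sqrt((u / spec$axes[1])^2 + (v / spec$axes[2])^2)
      lim <- 1 + spec$boundary_wobble *
        sin(spec$wobble_lobes * atan2(v, u) + spec$wobble_phase)
      if (rho <= lim) m[i, j] <- 1L
    }
  }
  m
}

# Sliding-window median with replicate padding, plain loops.
oracle_median <- function(image, window) {
  r <- (window - 1) %/% 2
  h <- nrow(image); w <- ncol(image)
  out <- image
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - r):(i + r), 1), h)
      ci <- pmin(pmax((j - r):(j + r), 1), w)
      out[i, j] <- median(image[ri, ci])
    }
  }
  out
}

# Pair-counting GLCM oracle: explicit double loop over pixels.
oracle_glcm <- function(image, offset, levels, mask = NULL, range = c(0, 255)) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(mask)) mask <- matrix(1L, h, w)
  q <- pmin(pmax(floor((image - range[1]) / (range[2] - range[1] + 1) * levels) + 1, 1), levels)
  counts <- matrix(0, levels, levels)
  dx <- offset[1]; dy <- offset[2]
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w &&
          mask[i, j] == 1 && mask[i2, j2] == 1) {
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      }
    }
  }
  counts <- counts + t(counts)
  counts / sum(counts)
}

# Classic flood fill accepting pixels within tol of the seed intensity
# (equivalent to the running-mean criterion on two-level images).
oracle_flood_fill <- function(image, seed, tol, connectivity = 8) {
  h <- nrow(image); w <- ncol(image)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  ref <- image[seed[1], seed[2]]
  mask <- matrix(0L, h, w)
  mask[seed[1], seed[2]] <- 1L
  stack <- list(seed)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (o in offs) {
      q <- p + o
      if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
          mask[q[1], q[2]] == 0L && abs(image[q[1], q[2]] - ref) <= tol) {
        mask[q[1], q[2]] <- 1L
        stack[[length(stack) + 1]] <- q
      }
    }
  }
  mask
}

# Reflection-counting asymmetry oracle: per-pixel fold across each principal
# axis (moments computed by explicit summation), symmetric difference halved.
oracle_asymmetry <- function(mask) {
  pts <- which(mask == 1L, arr.ind = TRUE)
  n <- nrow(pts)
  ctr <- c(sum(pts[, 1]) / n, sum(pts[, 2]) / n)
  sxx <- sum((pts[, 1] - ctr[1])^2) / n
  syy <- sum((pts[, 2] - ctr[2])^2) / n
  sxy <- sum((pts[, 1] - ctr[1]) * (pts[, 2] - ctr[2])) / n
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)$vectors
  h <- nrow(mask); w <- ncol(mask)
  per_axis <- numeric(2)
  for (k in 1:2) {
    v <- ev[, k]
    refl <- matrix(0L, h, w)
    oob <- 0
    for (r in seq_len(n)) {
      d <- c(pts[r, 1] - ctr[1], pts[r, 2] - ctr[2])
      proj <- sum(d * v)
      rp <- round(ctr + 2 * proj * v - d)
      if (rp[1] >= 1 && rp[1] <= h && rp[2] >= 1 && rp[2] <= w) {
        refl[rp[1], rp[2]] <- 1L
      } else {
        oob <- oob + 1
      }
    }
    dak <- (sum(abs(mask - refl)) + oob) / 2
    per_axis[k] <- 100 * dak / n
  }
  mean(per_axis)
}

# Brute-force confusion tally.
oracle_confusion <- function(truth, pred, positive) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    else if (truth[i] != positive && pred[i] == positive) fp <- fp + 1L
    else if (truth[i] == positive && pred[i] != positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
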