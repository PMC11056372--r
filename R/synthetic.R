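# Synthetic dermoscopy-image generator: perturbed-ellipse lesions darker than
# the surrounding skin, optional curvilinear hair artifacts, exact ground-truth
# masks and benign/malignant labels with class-conditional shape and texture
# gaps (asymmetry, border wobble, texture noise).

#' Specify a synthetic lesion
#'
#' A lesion is modelled as an ellipse whose radius is modulated by a sinusoidal
#' boundary perturbation: a point at ellipse-frame polar angle theta lies inside
#' when its normalized elliptical radius is at most
#' `1 + boundary_wobble * sin(wobble_lobes * theta + wobble_phase)`.
#' `boundary_wobble = 0` gives an exact ellipse; increasing amplitude and lobe
#' count produce the ragged borders typical of melanomas.
#'
#' @param center numeric length-2, lesion centre as (row, col) pixel coordinates.
#' @param axes numeric length-2, major/minor semi-axis lengths in pixels.
#' @param rotation rotation of the major axis in degrees.
#' @param boundary_wobble amplitude fraction in `[0, 1)` of the radial
#'   sinusoidal perturbation.
#' @param wobble_lobes integer number of perturbation lobes.
#' @param wobble_phase phase of the perturbation in radians.
#' @param lesion_color,skin_color RGB triples in `[0, 255]`.
#' @param texture_noise_sd standard deviation (gray levels) of the i.i.d.
#'   Gaussian pixel noise added per channel.
#' @param label `"benign"` or `"malignant"`.
#' @return a `lesion_spec` object (named list).
#' @export
lesion_spec <- function(center = c(128, 128), axes = c(45, 40), rotation = 0,
                        boundary_wobble = 0, wobble_lobes = 5L, wobble_phase = 0,
                        lesion_color = c(110, 75, 65),
                        skin_color = c(205, 165, 145),
                        texture_noise_sd = 8, label = c("benign", "malignant")) {
  label <- match.arg(label)
  if (any(axes <= 0)) stop("`axes` must be positive", call. = FALSE)
  if (boundary_wobble < 0 || boundary_wobble >= 1) {
    stop("`boundary_wobble` must lie in [0, 1)", call. = FALSE)
  }
  if (any(lesion_color < 0 | lesion_color > 255) || any(skin_color < 0 | skin_color > 255)) {
    stop("colors must lie in [0, 255]", call. = FALSE)
  }
  if (texture_noise_sd < 0) stop("`texture_noise_sd` must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 rotation = rotation, boundary_wobble = boundary_wobble,
                 wobble_lobes = as.integer(wobble_lobes), wobble_phase = wobble_phase,
                 lesion_color = as.numeric(lesion_color),
                 skin_color = as.numeric(skin_color),
                 texture_noise_sd = texture_noise_sd, label = label),
            class = "lesion_spec")
}

# Rasterize the perturbed-ellipse region of a lesion_spec on a h x w grid.
rasterize_lesion <- function(spec, height, width) {
  rr <- matrix(seq_len(height), height, width) - spec$center[1]
  cc <- matrix(seq_len(width), height, width, byrow = TRUE) - spec$center[2]
  th <- -spec$rotation * pi / 180
  u <- rr * cos(th) - cc * sin(th)
  v <- rr * sin(th) + cc * cos(th)
  rho <- sqrt((u / spec$axes[1])^2 + (v / spec$axes[2])^2)
  theta <- atan2(v, u)
  lim <- 1 + spec$boundary_wobble * sin(spec$wobble_lobes * theta + spec$wobble_phase)
  m <- (rho <= lim) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Generate one synthetic dermoscopy-like image with exact ground truth
#'
#' Renders the lesion of `spec` (darker pigmented blob) over uniform skin, adds
#' i.i.d. Gaussian texture noise per channel (clipped to `[0, 255]` and rounded
#' to 8-bit), and returns the image together with the exact rasterized mask.
#' Deterministic for fixed `seed`.
#'
#' @param spec a [lesion_spec()].
#' @param width,height image size in pixels.
#' @param seed integer RNG seed.
#' @return a `synthetic_sample`: list with `image` (`h x w x 3`, 0..255),
#'   `truth_mask` (`h x w` of `{0,1}`), and `spec`.
#' @export
generate_lesion_image <- function(spec, width = 256L, height = 256L, seed = 1L) {
  stopifnot(inherits(spec, "lesion_spec"))
  reach <- max(spec$axes) * (1 + spec$boundary_wobble)
  if (spec$center[1] - reach < 1 || spec$center[1] + reach > height ||
      spec$center[2] - reach < 1 || spec$center[2] + reach > width) {
    stop("lesion geometry does not fit inside the image", call. = FALSE)
  }
  set.seed(seed)
  mask <- rasterize_lesion(spec, height, width)
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) {
    base <- ifelse(mask == 1L, spec$lesion_color[ch], spec$skin_color[ch])
    img[, , ch] <- clamp255(round(base + rnorm(height * width, sd = spec$texture_noise_sd)))
  }
  structure(list(image = img, truth_mask = mask, spec = spec),
            class = "synthetic_sample")
}

# Rasterize one quadratic Bezier hair stroke; returns pixel indices (matrix
# rows of (row, col)) covered by a stroke of the given width.
rasterize_stroke <- function(p0, p1, p2, width_px, height, width) {
  len <- sum(sqrt(diff(c(p0[1], p1[1], p2[1]))^2 + diff(c(p0[2], p1[2], p2[2]))^2))
  t <- seq(0, 1, length.out = max(16L, ceiling(3 * len)))
  b <- function(i) (1 - t)^2 * p0[i] + 2 * (1 - t) * t * p1[i] + t^2 * p2[i]
  rr <- b(1); cc <- b(2)
  r <- (width_px - 1) / 2
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= max(r, 0.5)^2 + 1e-9, , drop = FALSE]
  pts <- unique(cbind(
    rep(round(rr), nrow(off)) + rep(off$dr, each = length(rr)),
    rep(round(cc), nrow(off)) + rep(off$dc, each = length(cc))
  ))
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= height & pts[, 2] >= 1 & pts[, 2] <= width, , drop = FALSE]
  pts
}

#' Overlay curvilinear hair artifacts on a synthetic sample
#'
#' Composites `n_hairs` dark strokes (random quadratic Bezier paths, width
#' 1–3 px) over the image; the ground-truth mask is unchanged. The union of
#' stroke pixels is recorded in the returned sample as `hair_mask`.
#'
#' @param sample a `synthetic_sample` from [generate_lesion_image()].
#' @param n_hairs number of strokes (>= 0).
#' @param seed integer RNG seed.
#' @param hair_color RGB triple of the stroke colour.
#' @return the modified `synthetic_sample` (with a `hair_mask` element).
#' @export
add_hair_artifacts <- function(sample, n_hairs, seed = 1L,
                               hair_color = c(40, 28, 22)) {
  stopifnot(inherits(sample, "synthetic_sample"))
  if (n_hairs < 0) stop("`n_hairs` must be >= 0", call. = FALSE)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  hair_mask <- matrix(0L, h, w)
  if (n_hairs == 0) {
    sample$hair_mask <- hair_mask
    return(sample)
  }
  set.seed(seed)
  img <- sample$image
  for (k in seq_len(n_hairs)) {
    # endpoints near opposite borders so strokes span the field of view
    p0 <- c(runif(1, 1, h), runif(1, 1, w * 0.25))
    p2 <- c(runif(1, 1, h), runif(1, w * 0.75, w))
    if (runif(1) < 0.5) { tmp <- p0[1]; p0[1] <- p0[2] / w * h; p0[2] <- tmp / h * w
                          tmp <- p2[1]; p2[1] <- p2[2] / w * h; p2[2] <- tmp / h * w }
    p1 <- c(runif(1, 1, h), runif(1, 1, w))
    wd <- sample.int(3L, 1L)
    pts <- rasterize_stroke(p0, p1, p2, wd, h, w)
    if (nrow(pts) == 0) next
    hair_mask[pts] <- 1L
    jitter <- rnorm(3, sd = 4)
    for (ch in 1:3) img[, , ch][pts] <- clamp255(round(hair_color[ch] + jitter[ch]))
  }
  sample$image <- img
  sample$hair_mask <- hair_mask
  sample
}

#' Generate a labelled synthetic dataset with class-conditional feature gaps
#'
#' Benign lesions are drawn near-symmetric (low boundary wobble, axis ratio
#' close to 1) with mild texture noise; malignant lesions are asymmetric,
#' wobbly-bordered, darker and noisier. These gaps make the classes separable
#' in ABCD + GLCM feature space, mirroring the clinical contrast the ABCD rule
#' encodes. Hair artifacts are overlaid at a Poisson-distributed rate.
#'
#' @param n_benign,n_malignant per-class sample counts (>= 0).
#' @param seed integer RNG seed.
#' @param width,height image size in pixels.
#' @param hair_rate mean number of hairs per image (Poisson); 0 disables hair.
#' @return list of `synthetic_sample` objects, benign first.
#' @export
generate_dataset <- function(n_benign, n_malignant, seed = 1L,
                             width = 256L, height = 256L, hair_rate = 4) {
  if (n_benign < 0 || n_malignant < 0) stop("counts must be >= 0", call. = FALSE)
  n <- n_benign + n_malignant
  if (n == 0) return(list())
  set.seed(seed)
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  sample_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    malignant <- labels[i] == "malignant"
    a <- if (malignant) runif(1, 40, 62) else runif(1, 35, 55)
    ratio <- if (malignant) runif(1, 0.45, 0.85) else runif(1, 0.8, 1.0)
    wob <- if (malignant) runif(1, 0.15, 0.35) else runif(1, 0, 0.05)
    lobes <- if (malignant) sample(5:9, 1) else sample(3:6, 1)
    noise <- if (malignant) runif(1, 18, 30) else runif(1, 5, 10)
    lcol <- if (malignant) c(70, 45, 45) + rnorm(3, sd = 10) else c(110, 75, 65) + rnorm(3, sd = 8)
    scol <- c(205, 165, 145) + rnorm(3, sd = 6)
    reach <- a * (1 + wob)
    ctr <- c(height / 2, width / 2) + runif(2, -10, 10)
    # shrink if the jittered geometry would clip the border
    max_reach <- min(ctr[1] - 2, height - ctr[1] - 1, ctr[2] - 2, width - ctr[2] - 1)
    if (reach > max_reach) a <- a * max_reach / reach
    spec <- lesion_spec(center = ctr, axes = c(a, a * ratio),
                        rotation = runif(1, 0, 180), boundary_wobble = wob,
                        wobble_lobes = lobes, wobble_phase = runif(1, 0, 2 * pi),
                        lesion_color = clamp255(lcol), skin_color = clamp255(scol),
                        texture_noise_sd = noise, label = labels[i])
    s <- generate_lesion_image(spec, width, height, seed = sample_seeds[2L * i - 1L])
    if (hair_rate > 0) {
      set.seed(sample_seeds[2L * i - 1L])
      nh <- rpois(1, hair_rate)
      s <- add_hair_artifacts(s, nh, seed = sample_seeds[2L * i])
    }
    out[[i]] <- s
  }
  out
}

#' Write a synthetic dataset to disk as PNG pairs plus a CSV manifest
#'
#' @param samples list of `synthetic_sample` objects.
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the manifest.
#' @return tibble manifest with columns `path`, `mask_path`, `label`, `seed`.
#' @export
write_dataset <- function(samples, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    img_path <- file.path(dir, sprintf("sample_%03d.png", i))
    mask_path <- file.path(dir, sprintf("sample_%03d_mask.png", i))
    write_image(samples[[i]]$image, img_path)
    write_mask(samples[[i]]$truth_mask, mask_path)
    tibble::tibble(path = img_path, mask_path = mask_path,
                   label = samples[[i]]$spec$label, seed = seed)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
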