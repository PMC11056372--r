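# ABCD-rule shape and colour descriptors: asymmetry index, border
# irregularity, colour variance in HSV, area, equivalent diameter, perimeter
# and roundness.

mask_points <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  idx
}

# Population second moments of the foreground pixel coordinates.
mask_moments <- function(mask) {
  pts <- mask_points(mask)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cv <- crossprod(d) / nrow(pts)
  ev <- eigen(cv, symmetric = TRUE)
  list(centroid = ctr, values = pmax(ev$values, 0), vectors = ev$vectors,
       n = nrow(pts))
}

reflect_mask_across_axis <- function(mask, centroid, direction) {
  pts <- mask_points(mask)
  d <- sweep(pts, 2, centroid)
  v <- direction / sqrt(sum(direction^2))
  # reflection matrix 2 v v^T - I
  R <- 2 * tcrossprod(v) - diag(2)
  refl <- d %*% t(R)
  ref_pts <- round(sweep(refl, 2, centroid, "+"))
  h <- nrow(mask); w <- ncol(mask)
  ok <- ref_pts[, 1] >= 1 & ref_pts[, 1] <= h & ref_pts[, 2] >= 1 & ref_pts[, 2] <= w
  out <- matrix(0L, h, w)
  out[ref_pts[ok, , drop = FALSE]] <- 1L
  list(mask = out, n_out_of_bounds = sum(!ok))
}

#' Asymmetry index (ASI)
#'
#' The mask is folded across each principal axis (major and minor, from the
#' second moments of the foreground pixels); the non-overlap area between the
#' mask and its reflection, halved, is expressed as a percentage of the lesion
#' area: `ASI = 100 * dAK / AL`. The mean over the two axes is returned;
#' per-axis values are attached as the `"per_axis"` attribute.
#'
#' @param mask binary matrix (nonempty).
#' @return percentage in `[0, 100]` with a `"per_axis"` attribute.
#' @export
asymmetry_index <- function(mask) {
  assert_mask(mask)
  mm <- mask_moments(mask)
  area <- mm$n
  per_axis <- vapply(1:2, function(k) {
    refl <- reflect_mask_across_axis(mask, mm$centroid, mm$vectors[, k])
    dak <- (sum(abs(mask - refl$mask)) + refl$n_out_of_bounds) / 2
    100 * dak / area
  }, numeric(1))
  names(per_axis) <- c("major", "minor")
  structure(mean(per_axis), per_axis = per_axis)
}

#' Border irregularity index
#'
#' `I = (a * b / (2 * pi * (a^2 + b^2))) * (P^2 / A)` where `a`, `b` are the
#' major/minor semi-axis lengths of the second-moment ellipse fit, `P` the
#' perimeter and `A` the area. Equals 1 for a perfect circle and grows with
#' boundary raggedness.
#'
#' @param mask binary matrix, single connected component.
#' @return unitless score.
#' @export
border_irregularity <- function(mask) {
  assert_mask(mask)
  mm <- mask_moments(mask)
  a <- 2 * sqrt(mm$values[1]); b <- 2 * sqrt(mm$values[2])
  if (b < 0.5) stop("degenerate (line-like) mask", call. = FALSE)
  P <- perimeter(mask)
  A <- mm$n
  (a * b / (2 * pi * (a^2 + b^2))) * P^2 / A
}

#' Per-channel HSV colour variance of the lesion
#'
#' Lesion pixels are converted from RGB to HSV. Hue, being an angle, is
#' summarized by its circular variance (`1 - mean resultant length`, in
#' `[0, 1]`); saturation and value are scaled to 0..255 and summarized by
#' their population variance.
#'
#' @param image RGB array.
#' @param mask binary matrix (nonempty).
#' @return named numeric `c(h =, s =, v =)`.
#' @export
color_variance <- function(image, mask) {
  assert_rgb(image); assert_mask(mask)
  pts <- mask_points(mask)
  lin <- (pts[, 2] - 1L) * nrow(mask) + pts[, 1]
  rgb <- rbind(image[, , 1][lin], image[, , 2][lin], image[, , 3][lin])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  ang <- 2 * pi * hsv[1, ]
  rbar <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  pvar <- function(x) mean((x - mean(x))^2)
  c(h = 1 - rbar, s = pvar(hsv[2, ] * 255), v = pvar(hsv[3, ] * 255))
}

#' Lesion area in pixels
#'
#' @param mask binary matrix.
#' @return foreground pixel count.
#' @export
area_of_object <- function(mask) {
  assert_mask(mask)
  sum(mask == 1L)
}

#' Equivalent-circle diameter
#'
#' `sqrt(4 * area / pi)`: the diameter of the circle with the lesion's area.
#'
#' @param mask binary matrix.
#' @return diameter in px (0 for an empty mask).
#' @export
lesion_diameter <- function(mask) {
  sqrt(4 * area_of_object(mask) / pi)
}

#' Boundary perimeter of a mask
#'
#' The ordered outer boundary is traced and consecutive steps are summed with
#' the Proffitt–Rosen corner-corrected weights (0.948 for orthogonal steps,
#' 1.343 for diagonal steps), which are nearly unbiased for smooth digitized
#' shapes.
#'
#' @param mask binary matrix, single connected component, nonempty.
#' @return boundary length in px.
#' @export
perimeter <- function(mask) {
  assert_mask(mask)
  if (!any(mask == 1L)) stop("mask is empty", call. = FALSE)
  if (sum(mask) == 1L) return(0.948 * 4 / 4)  # single pixel: degenerate
  ocs <- EBImage::ocontour(mask)
  oc <- ocs[[which.max(vapply(ocs, nrow, integer(1)))]]
  if (nrow(oc) < 2) return(0)
  d <- sqrt(rowSums((oc - oc[c(2:nrow(oc), 1), , drop = FALSE])^2))
  sum(ifelse(d < 1.2, 0.948, 1.343))
}

#' Roundness (circularity)
#'
#' `sqrt(4 * pi * area / perimeter^2)`: 1 for a perfect circle, smaller for
#' elongated or ragged shapes.
#'
#' @param mask binary matrix, single connected component.
#' @return unitless score.
#' @export
roundness <- function(mask) {
  A <- area_of_object(mask)
  if (A == 0) stop("mask is empty", call. = FALSE)
  P <- perimeter(mask)
  if (P <= 0) stop("degenerate mask", call. = FALSE)
  sqrt(4 * pi * A / P^2)
}
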