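# Assembly of the full per-lesion feature vector: 20 GLCM statistics averaged
# over the four standard offsets, plus six ABCD-derived descriptors.

glcm_default_offsets <- function() list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))

#' Names and order of the 26 lesion features
#'
#' @return character vector of length 26.
#' @export
feature_names <- function() {
  c(names(glcm_statistics(structure(matrix(c(1, 0, 0, 0), 2, 2), class = c("glcm", "matrix")))),
    "asymmetry_index", "border_irregularity", "color_variance",
    "area", "diameter", "roundness")
}

#' Extract the full feature vector for one lesion
#'
#' Computes the 20 GLCM texture statistics (within-mask co-occurrence,
#' averaged over the offsets `(1,0)`, `(0,1)`, `(1,1)`, `(1,-1)`) and the six
#' ABCD-derived descriptors: mean-axis asymmetry index, border irregularity,
#' a scalar colour variance (mean of the per-channel HSV variances, with
#' saturation/value variances rescaled to `[0, 1]` to be commensurate with the
#' circular hue variance), area, equivalent diameter and roundness.
#'
#' @param image RGB array.
#' @param gray preprocessed grayscale matrix (texture source).
#' @param mask binary lesion mask (nonempty).
#' @param glcm_levels quantization levels for the GLCM.
#' @param glcm_offsets list of `(dx, dy)` offsets to average over.
#' @return named numeric vector of length 26 in the fixed [feature_names()]
#'   order; an error names any non-finite feature.
#' @export
extract_feature_vector <- function(image, gray, mask, glcm_levels = 8L,
                                   glcm_offsets = glcm_default_offsets()) {
  assert_rgb(image); assert_gray(gray); assert_mask(mask)
  if (!all(dim(gray) == dim(mask)) || !all(dim(image)[1:2] == dim(mask))) {
    stop("image, gray and mask dimensions must agree", call. = FALSE)
  }
  stats_list <- lapply(glcm_offsets, function(off) {
    glcm_statistics(compute_glcm(gray, mask, offset = off, levels = glcm_levels))
  })
  glcm_feats <- Reduce(`+`, stats_list) / length(stats_list)
  cv <- color_variance(image, mask)
  color_scalar <- mean(c(cv[["h"]], cv[["s"]] / 255^2, cv[["v"]] / 255^2))
  out <- c(glcm_feats,
           asymmetry_index = as.numeric(asymmetry_index(mask)),
           border_irregularity = border_irregularity(mask),
           color_variance = color_scalar,
           area = area_of_object(mask),
           diameter = lesion_diameter(mask),
           roundness = roundness(mask))
  bad <- names(out)[!is.finite(out)]
  if (length(bad) > 0) {
    stop(sprintf("non-finite feature(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Extract a feature table from a list of samples
#'
#' Convenience wrapper mapping [extract_feature_vector()] over samples. Each
#' sample is a list with `image`, a lesion `mask` (or `truth_mask`), and
#' optionally a precomputed `gray` image; otherwise the raw grayscale
#' conversion is used as the texture source.
#'
#' @param samples list of samples.
#' @param ids optional character ids (default `sample_001`, ...).
#' @param ... passed to [extract_feature_vector()].
#' @return tibble with columns `id`, `label` (NA when unknown) and the 26
#'   features.
#' @export
extract_features <- function(samples, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_along(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    mask <- if (!is.null(s$mask)) s$mask else s$truth_mask
    gray <- if (!is.null(s$gray)) s$gray else to_grayscale(s$image)
    fv <- extract_feature_vector(s$image, gray, mask, ...)
    label <- if (!is.null(s$spec$label)) s$spec$label else
      if (!is.null(s$label)) s$label else NA_character_
    tibble::tibble(id = ids[i], label = label, !!!as.list(fv))
  })
  dplyr::bind_rows(rows)
}
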