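# Binary-classification evaluation: confusion matrix, the seven-metric suite
# (accuracy, sensitivity, specificity, precision, F1/Dice, Jaccard, MCC), and
# a reconstruction oracle recovering integer confusion matrices from printed
# percentage metrics.

#' Build a 2x2 confusion matrix
#'
#' @param true_labels,predicted_labels equal-length label vectors drawn from
#'   at most two classes.
#' @param positive the positive class.
#' @return a `confusion_matrix`: list of integer counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, positive) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  classes <- unique(c(true_labels, predicted_labels))
  if (length(classes) > 2) stop("more than two classes present", call. = FALSE)
  if (!positive %in% classes) classes <- c(classes, positive)
  tp <- sum(true_labels == positive & predicted_labels == positive)
  fp <- sum(true_labels != positive & predicted_labels == positive)
  fn <- sum(true_labels == positive & predicted_labels != positive)
  tn <- sum(true_labels != positive & predicted_labels != positive)
  new_confusion(tp, fp, fn, tn, positive = positive)
}

new_confusion <- function(tp, fp, fn, tn, positive = NA_character_) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix> TP=%d FP=%d FN=%d TN=%d (total %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' The seven evaluation metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, precision `TP/(TP+FP)`, F1 (Dice) as the
#' harmonic mean of precision and recall, Jaccard as `F1/(2-F1)`, and the
#' Matthews correlation coefficient. All arithmetic is on exact integer
#' counts with floating division at the last step. A metric whose denominator
#' is zero is reported as `NA` and named in the `"undefined"` attribute,
#' never silently zero.
#'
#' @param cm a `confusion_matrix`.
#' @return one-row tibble with the seven metrics (and an `"undefined"`
#'   attribute listing any undefined ones).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  accuracy <- safe(tp + tn, total, "accuracy")
  sensitivity <- safe(tp, tp + fn, "sensitivity")
  specificity <- safe(tn, fp + tn, "specificity")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(precision) || is.na(sensitivity)) {
    undefined <- c(undefined, "f1"); NA_real_
  } else if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * sensitivity / (precision + sensitivity)
  jaccard <- if (is.na(f1)) { undefined <- c(undefined, "jaccard"); NA_real_ } else f1 / (2 - f1)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); NA_real_ } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }
  out <- tibble::tibble(accuracy = accuracy, sensitivity = sensitivity,
                        specificity = specificity, precision = precision,
                        f1 = f1, jaccard = jaccard, mcc = mcc)
  attr(out, "undefined") <- unique(undefined)
  out
}

#' Jaccard index from the F1 (Dice) score
#'
#' The set identity `J = F1 / (2 - F1)`.
#'
#' @param f1 F1 score in `[0, 1]`.
#' @return Jaccard index.
#' @export
jaccard_from_f1 <- function(f1) {
  if (any(f1 < 0 | f1 > 1)) stop("`f1` must lie in [0, 1]", call. = FALSE)
  f1 / (2 - f1)
}

decimal_places <- function(v, max_d = 4L) {
  for (d in 0:max_d) if (abs(v - round(v, d)) < 1e-9) return(d)
  max_d
}

# Does computed percentage x print as v (given v's decimals), under either
# round-half-up or truncation?
matches_printed <- function(x, v) {
  d <- decimal_places(v)
  f <- 10^d
  round_half_up <- floor(x * f + 0.5) / f
  truncated <- floor(x * f + 1e-9) / f
  abs(round_half_up - v) < 1e-9 | abs(truncated - v) < 1e-9
}

#' Reconstruct an integer confusion matrix from printed percentage metrics
#'
#' Exhaustively searches nonnegative integer `(TP, FP, FN, TN)` with total at
#' most `max_total` for matrices whose computed precision, sensitivity and
#' specificity — rounded (half-up) or truncated to the printed number of
#' decimals — equal the printed percentages. Returns the match with the
#' smallest total (ties broken by smallest TP), or `NULL` with a warning when
#' no consistent matrix exists.
#'
#' @param precision_pct,sensitivity_pct,specificity_pct printed percentages
#'   in `[0, 100]`.
#' @param max_total search bound on `TP+FP+FN+TN` (>= 2).
#' @return a `confusion_matrix`, or `NULL` when no consistent matrix exists.
#' @export
reconstruct_confusion_from_metrics <- function(precision_pct, sensitivity_pct,
                                               specificity_pct, max_total = 200L) {
  vals <- c(precision_pct, sensitivity_pct, specificity_pct)
  if (any(vals < 0 | vals > 100)) stop("percentages must lie in [0, 100]", call. = FALSE)
  if (max_total < 2) stop("`max_total` must be >= 2", call. = FALSE)
  # candidate (TP, FN) pairs compatible with printed sensitivity
  grid2 <- function(lim) {
    g <- expand.grid(a = 0:lim, b = 0:lim)
    g[g$a + g$b <= lim & g$a + g$b > 0, , drop = FALSE]
  }
  g <- grid2(max_total)
  sens_ok <- g[matches_printed(100 * g$a / (g$a + g$b), sensitivity_pct), , drop = FALSE]
  prec_ok <- g[matches_printed(100 * g$a / (g$a + g$b), precision_pct), , drop = FALSE]
  spec_ok <- g[matches_printed(100 * g$a / (g$a + g$b), specificity_pct), , drop = FALSE]
  names(sens_ok) <- c("tp", "fn"); names(prec_ok) <- c("tp", "fp")
  names(spec_ok) <- c("tn", "fp")
  cand <- merge(sens_ok, prec_ok, by = "tp")
  if (nrow(cand) > 0) cand <- merge(cand, spec_ok, by = "fp")
  if (nrow(cand) > 0) {
    cand$total <- cand$tp + cand$fp + cand$fn + cand$tn
    cand <- cand[cand$total <= max_total, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    warning("no consistent confusion matrix within max_total", call. = FALSE)
    return(NULL)
  }
  cand <- cand[order(cand$total, cand$tp), , drop = FALSE]
  best <- cand[1, ]
  new_confusion(best$tp, best$fp, best$fn, best$tn)
}

#' Published reference performance of the ANN and SVM dermoscopy classifiers
#'
#' The printed percentage metrics of the reference automated dermoscopy
#' system that this package re-implements (ANN and SVM variants evaluated on
#' the PH2 dataset with an 80/20 split). Used by
#' [verify_reported_performance()] to demonstrate the internal consistency of
#' the metric definitions.
#'
#' @return tibble with one row per classifier: printed precision, accuracy,
#'   sensitivity, specificity (percent), F1, Jaccard, and MCC (percent).
#' @export
reference_performance <- function() {
  tibble::tibble(
    algorithm = c("ann", "svm"),
    precision_pct = c(96, 76),
    accuracy_pct = c(94, 74),
    sensitivity_pct = c(92.30, 73.07),
    specificity_pct = c(95.83, 75),
    f1 = c(0.94, 0.74),
    jaccard = c(0.886, 0.587),
    mcc_pct = c(88.5, 48)
  )
}

#' Verify the reported reference metrics against the metric implementation
#'
#' For each reference row, reconstructs the minimal integer confusion matrix
#' consistent with the printed precision/sensitivity/specificity
#' ([reconstruct_confusion_from_metrics()]), recomputes all seven metrics
#' from it, and compares with the printed values under the printed-precision
#' rounding-or-truncation convention. The Jaccard comparison follows the
#' reference arithmetic, which applies `F1/(2-F1)` to the printed
#' (2-decimal) F1 as given in the reference table — not to a re-rounding of
#' the exact F1, which differs when the printed F1 was truncated.
#'
#' @param reference tibble in the [reference_performance()] layout.
#' @param max_total search bound for the reconstruction.
#' @return tibble with the reconstructed counts, recomputed metrics, and
#'   per-metric match flags.
#' @export
verify_reported_performance <- function(reference = reference_performance(),
                                        max_total = 200L) {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    cm <- reconstruct_confusion_from_metrics(r$precision_pct, r$sensitivity_pct,
                                             r$specificity_pct, max_total)
    if (is.null(cm)) {
      return(tibble::tibble(algorithm = r$algorithm, tp = NA_integer_,
                            fp = NA_integer_, fn = NA_integer_, tn = NA_integer_))
    }
    m <- compute_metrics(cm)
    tibble::tibble(
      algorithm = r$algorithm,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      accuracy_pct = 100 * m$accuracy, f1 = m$f1,
      jaccard_from_printed_f1 = jaccard_from_f1(r$f1),
      mcc_pct = 100 * m$mcc,
      accuracy_match = matches_printed(100 * m$accuracy, r$accuracy_pct),
      f1_match = matches_printed(100 * m$f1, 100 * r$f1),
      jaccard_match = matches_printed(100 * jaccard_from_f1(r$f1),
                                      100 * r$jaccard),
      mcc_match = matches_printed(100 * m$mcc, r$mcc_pct)
    )
  })
  dplyr::bind_rows(rows)
}
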