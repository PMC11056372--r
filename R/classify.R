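# Benign/malignant classification of lesion feature vectors: stratified
# splitting, a feed-forward neural network (single hidden layer, logistic
# activations) and a kernel SVM, with shared feature standardization.

# The namespace imports below guarantee that nnet's and e1071's predict
# methods are registered even in sessions that only load a serialized model
# and never call the trainers.
#' @importFrom nnet nnet
#' @importFrom e1071 svm
NULL

feature_columns <- function(data) {
  setdiff(names(data), c("id", "label"))
}

#' Stratified train/test split
#'
#' Randomly partitions a labelled feature table into train and test subsets,
#' stratified by `label`, deterministic per seed. The per-class train counts
#' are `round(fraction * n_class)`, so class proportions are preserved to
#' within one sample.
#'
#' @param data tibble with a `label` column (two classes, >= 2 samples each).
#' @param train_fraction fraction in `(0, 1)` assigned to training.
#' @param seed integer RNG seed.
#' @return list with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (!"label" %in% names(data)) stop("`data` must have a `label` column", call. = FALSE)
  counts <- table(data$label)
  if (any(counts < 2)) stop("each class needs >= 2 samples for stratification", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(data$label == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE])
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)[, , drop = FALSE]
}

check_training_data <- function(data) {
  cols <- feature_columns(data)
  x <- as.matrix(data[, cols, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite feature values in training data", call. = FALSE)
  classes <- sort(unique(data$label))
  if (length(classes) != 2) stop("training data must contain exactly 2 classes", call. = FALSE)
  list(x = x, y = data$label, cols = cols, classes = classes)
}

#' Train a feed-forward neural network classifier
#'
#' Standardizes the features (training-set center/scale, reused verbatim at
#' prediction time), holds out a validation fraction, and fits a single
#' hidden-layer network with logistic activations and a single sigmoid output
#' ([nnet::nnet]). Non-convergence within `maxit` is recorded as a warning
#' flag in the model, not an error.
#'
#' @param train labelled feature tibble (columns `id`, `label`, features).
#' @param hidden hidden layer size.
#' @param maxit maximum training epochs.
#' @param decay weight decay regularization.
#' @param val_fraction fraction of the training set held out to report
#'   validation accuracy.
#' @param seed integer RNG seed (weight initialization and validation split).
#' @return a `dermoscan_classifier` of kind `"ann"`.
#' @export
train_ann <- function(train, hidden = 16L, maxit = 500L, decay = 0.01,
                      val_fraction = 0.1, seed = 1L) {
  td <- check_training_data(train)
  set.seed(seed)
  n <- nrow(td$x)
  n_val <- floor(val_fraction * n)
  val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)
  sc <- standardize_fit(td$x[fit_idx, , drop = FALSE])
  xs <- standardize_apply(td$x, sc)
  y <- as.integer(td$y == td$classes[2])
  fit <- nnet::nnet(xs[fit_idx, , drop = FALSE], y[fit_idx], size = hidden,
                    decay = decay, maxit = maxit, entropy = TRUE, trace = FALSE)
  val_acc <- if (length(val_idx) > 0) {
    mean((predict(fit, xs[val_idx, , drop = FALSE]) > 0.5) == (y[val_idx] == 1))
  } else NA_real_
  train_acc <- mean((predict(fit, xs[fit_idx, , drop = FALSE]) > 0.5) == (y[fit_idx] == 1))
  structure(list(kind = "ann", fit = fit, scaling = sc, classes = td$classes,
                 features = td$cols,
                 config = list(hidden = hidden, maxit = maxit, decay = decay,
                               val_fraction = val_fraction, seed = seed),
                 converged = fit$convergence == 0,
                 n_train = length(fit_idx), train_accuracy = train_acc,
                 val_accuracy = val_acc),
            class = c("dermoscan_ann", "dermoscan_classifier"))
}

#' Train a kernel SVM classifier
#'
#' Standardizes the features (training-set center/scale) and fits a support
#' vector machine ([e1071::svm]) with the given kernel.
#'
#' @param train labelled feature tibble.
#' @param kernel `"radial"` (default), `"linear"`, `"polynomial"` or
#'   `"sigmoid"`.
#' @param cost margin penalty parameter.
#' @param seed integer RNG seed.
#' @return a `dermoscan_classifier` of kind `"svm"`.
#' @export
train_svm <- function(train, kernel = "radial", cost = 1, seed = 1L) {
  td <- check_training_data(train)
  set.seed(seed)
  sc <- standardize_fit(td$x)
  xs <- standardize_apply(td$x, sc)
  yf <- factor(td$y, levels = td$classes)
  fit <- e1071::svm(xs, yf, kernel = kernel, cost = cost, scale = FALSE)
  train_acc <- mean(predict(fit, xs) == yf)
  structure(list(kind = "svm", fit = fit, scaling = sc, classes = td$classes,
                 features = td$cols,
                 config = list(kernel = kernel, cost = cost, seed = seed),
                 converged = TRUE, n_train = nrow(xs), train_accuracy = train_acc,
                 val_accuracy = NA_real_),
            class = c("dermoscan_svm", "dermoscan_classifier"))
}

classifier_newdata <- function(model, data) {
  if (is.data.frame(data)) {
    missing <- setdiff(model$features, names(data))
    if (length(missing) > 0) {
      stop(sprintf("missing feature column(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    x <- as.matrix(data[, model$features, drop = FALSE])
  } else {
    x <- as.matrix(data)
    if (ncol(x) != length(model$features)) {
      stop(sprintf("expected %d features, got %d", length(model$features), ncol(x)),
           call. = FALSE)
    }
    colnames(x) <- model$features
  }
  standardize_apply(x, model$scaling)
}

#' @export
predict.dermoscan_ann <- function(object, newdata, ...) {
  if (NROW(newdata) == 0) return(character(0))
  xs <- classifier_newdata(object, newdata)
  p <- as.vector(predict(object$fit, xs))
  object$classes[(p > 0.5) + 1L]
}

#' @export
predict.dermoscan_svm <- function(object, newdata, ...) {
  if (NROW(newdata) == 0) return(character(0))
  xs <- classifier_newdata(object, newdata)
  as.character(predict(object$fit, xs))
}

#' @export
print.dermoscan_classifier <- function(x, ...) {
  cat(sprintf("<dermoscan %s classifier>  %d features, %d training samples\n",
              toupper(x$kind), length(x$features), x$n_train))
  cat(sprintf("  classes: %s | train accuracy %.3f%s\n",
              paste(x$classes, collapse = " vs "), x$train_accuracy,
              if (!is.na(x$val_accuracy)) sprintf(" | validation accuracy %.3f", x$val_accuracy) else ""))
  invisible(x)
}

#' Tidy the per-feature scaling of a trained classifier
#'
#' @param x a `dermoscan_classifier`.
#' @param ... unused.
#' @return tibble with one row per feature: `feature`, `center`, `scale`.
#' @export
tidy.dermoscan_classifier <- function(x, ...) {
  tibble::tibble(feature = x$features,
                 center = unname(x$scaling$center),
                 scale = unname(x$scaling$scale))
}

#' One-row model summary of a trained classifier
#'
#' @param x a `dermoscan_classifier`.
#' @param ... unused.
#' @return tibble with `kind`, `n_train`, `n_features`, `train_accuracy`,
#'   `val_accuracy`, `converged`.
#' @export
glance.dermoscan_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_train = x$n_train,
                 n_features = length(x$features),
                 train_accuracy = x$train_accuracy,
                 val_accuracy = x$val_accuracy, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
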