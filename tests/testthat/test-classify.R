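# Small labelled feature tables with a controllable class gap.
make_clusters <- function(n_per_class, gap = 5, sd = 1, seed = 1,
                          labels = c("benign", "malignant")) {
  set.seed(seed)
  n <- 2 * n_per_class
  tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    label = rep(labels, each = n_per_class),
    f1 = rnorm(n, mean = rep(c(0, gap), each = n_per_class), sd = sd),
    f2 = rnorm(n, mean = rep(c(0, gap), each = n_per_class), sd = sd))
}

test_that("split_dataset stratifies 200 samples into 160/40 deterministically", {
  d <- make_clusters(100)
  sp <- split_dataset(d, 0.8, seed = 3)
  expect_identical(nrow(sp$train), 160L)
  expect_identical(nrow(sp$test), 40L)
  expect_identical(as.vector(table(sp$train$label)), c(80L, 80L))
  expect_identical(as.vector(table(sp$test$label)), c(20L, 20L))
  expect_identical(intersect(sp$train$id, sp$test$id), character(0))
  sp2 <- split_dataset(d, 0.8, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- split_dataset(d, 0.8, seed = 4)
  expect_false(identical(sp$train$id, sp3$train$id))
})

test_that("split_dataset preserves unbalanced class proportions within one", {
  d <- make_clusters(60)                            # 120 rows
  d$label <- rep(c("benign", "malignant"), c(80, 40))
  sp <- split_dataset(d, 0.8, seed = 1)
  expect_identical(sum(sp$train$label == "benign"), 64L)
  expect_identical(sum(sp$train$label == "malignant"), 32L)
  expect_error(split_dataset(d, 1.2), "train_fraction")
  expect_error(split_dataset(tibble::tibble(label = c("a", "a", "b"), x = 1:3)),
               ">= 2 samples")
})

test_that("the ANN separates well-separated clusters", {
  d <- make_clusters(100, gap = 5, seed = 5)
  sp <- split_dataset(d, 0.8, seed = 5)
  m <- train_ann(sp$train, seed = 5)
  expect_s3_class(m, "dermoscan_ann")
  pred <- predict(m, sp$test)
  expect_gte(mean(pred == sp$test$label), 0.95)
  expect_true(all(pred %in% c("benign", "malignant")))
})

test_that("a single perfectly informative feature drives the ANN to ~1", {
  set.seed(6)
  d <- tibble::tibble(id = sprintf("s%03d", 1:120),
                      label = rep(c("benign", "malignant"), each = 60),
                      f1 = rep(c(0, 1), each = 60) + rnorm(120, sd = 0.05))
  sp <- split_dataset(d, 0.8, seed = 6)
  m <- train_ann(sp$train, seed = 6)
  expect_gte(mean(predict(m, sp$test) == sp$test$label), 0.99)
})

test_that("ANN accuracy on permuted labels stays near chance over 20 seeds", {
  accs <- vapply(1:20, function(sd) {
    d <- make_clusters(30, gap = 5, seed = 100 + sd)
    set.seed(200 + sd)
    d$label <- sample(d$label)         # break the feature-label link
    sp <- split_dataset(d, 0.8, seed = sd)
    m <- train_ann(sp$train, seed = sd, maxit = 200)
    mean(predict(m, sp$test) == sp$test$label)
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("the SVM separates linear and XOR structure with matching kernels", {
  d <- make_clusters(100, gap = 6, seed = 7)
  sp <- split_dataset(d, 0.8, seed = 7)
  m <- train_svm(sp$train, kernel = "linear", seed = 7)
  expect_gte(mean(predict(m, sp$train) == sp$train$label), 0.99)
  expect_gte(mean(predict(m, sp$test) == sp$test$label), 0.95)

  # XOR: not linearly separable, radial kernel handles it
  set.seed(8)
  n <- 200
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  xor_d <- tibble::tibble(id = sprintf("s%03d", 1:n),
                          label = ifelse(x1 * x2 > 0, "benign", "malignant"),
                          f1 = x1, f2 = x2)
  xor_d <- xor_d[abs(x1 * x2) > 0.05, ]  # margin away from the axes
  mr <- train_svm(xor_d, kernel = "radial", cost = 10, seed = 8)
  expect_gte(mean(predict(mr, xor_d) == xor_d$label), 0.95)
})

test_that("prediction interface checks features and handles empty input", {
  d <- make_clusters(30, seed = 9)
  m <- train_ann(d, seed = 9)
  expect_identical(predict(m, d[0, ]), character(0))
  expect_error(predict(m, d[, c("id", "label", "f1")]), "missing feature")
  # matrix input with correct width works and matches data-frame input
  x <- as.matrix(d[, c("f1", "f2")])
  expect_identical(predict(m, x), predict(m, d))
  expect_error(predict(m, x[, 1, drop = FALSE]), "expected 2 features")
  # prediction is row-wise: a permutation permutes the output
  set.seed(12)
  perm <- sample(nrow(d))
  expect_identical(predict(m, d[perm, ]), predict(m, d)[perm])
})

test_that("training is deterministic per seed and records diagnostics", {
  d <- make_clusters(40, seed = 10)
  m1 <- train_ann(d, seed = 11)
  m2 <- train_ann(d, seed = 11)
  expect_identical(m1$fit$wts, m2$fit$wts)
  g <- glance(m1)
  expect_identical(g$kind, "ann")
  expect_identical(g$n_features, 2L)
  expect_true(g$train_accuracy >= 0 && g$train_accuracy <= 1)
  td <- tidy(m1)
  expect_identical(td$feature, c("f1", "f2"))
  # scaling equals the fit-subset mean/sd
  s <- train_svm(d, seed = 11)
  expect_equal(tidy(s)$center, colMeans(d[, c("f1", "f2")]), ignore_attr = TRUE)
  expect_equal(tidy(s)$scale, apply(d[, c("f1", "f2")], 2, sd), ignore_attr = TRUE)
  expect_error(train_ann(dplyr::mutate(d, label = "benign")), "2 classes")
})
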