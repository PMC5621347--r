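make_blobs <- function(n_per = 10, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  colnames(X) <- c("f1", "f2")
  list(X = as.data.frame(X), y = rep(c(0L, 1L), each = n_per))
}

all_specs <- function() {
  list(classifier_spec("decision_tree"),
       classifier_spec("svm", kernel = "linear"),
       classifier_spec("svm", kernel = "polynomial"),
       classifier_spec("svm", kernel = "rbf"),
       classifier_spec("discriminant"),
       classifier_spec("random_forest", seed = 3),
       classifier_spec("knn", k = 3))
}

test_that("every family separates two distant Gaussian blobs under LOOCV", {
  b <- make_blobs()
  for (spec in all_specs()) {
    res <- loocv(spec, b$X, b$y)
    expect_equal(loocv_accuracy(res), 1.0, info = spec$family)
  }
})

test_that("uniformly labelled data is predicted perfectly", {
  set.seed(2)
  X <- data.frame(f1 = rnorm(8), f2 = rnorm(8))
  res <- loocv(classifier_spec("decision_tree"), X, rep(2L, 8))
  expect_true(all(res$pred == 2L))
  expect_equal(loocv_accuracy(res), 1.0)
})

test_that("1-NN honours duplicated points and deterministic tie-breaks", {
  # duplicated points with different labels: under LOOCV the duplicate is
  # the zero-distance neighbour, so each point takes its twin's label
  X <- data.frame(f1 = c(0, 0, 5, 5, 9, 9), f2 = 0)
  y <- c(0L, 1L, 2L, 2L, 3L, 3L)
  res <- loocv(classifier_spec("knn", k = 1), X, y)
  expect_equal(res$pred, c(1L, 0L, 2L, 2L, 3L, 3L))

  # equidistant neighbours: the lower label wins the distance tie
  m <- fit_classifier(classifier_spec("knn", k = 1),
                      data.frame(f1 = c(-1, 1)), c(3L, 1L))
  expect_equal(predict_classifier(m, data.frame(f1 = 0)), 1L)
  # three-way vote tie at k = 3: one vote each, lowest label wins
  m2 <- fit_classifier(classifier_spec("knn", k = 3),
                       data.frame(f1 = c(-1, 1, 3)), c(2L, 1L, 4L))
  expect_equal(predict_classifier(m2, data.frame(f1 = 0)), 1L)
})

test_that("1-NN LOOCV equals the brute-force nearest-other-point oracle", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- sample(10:20, 1)
    y <- sample(0:4, n, replace = TRUE)
    # one feature: fold z-scoring is affine and cannot reorder neighbours,
    # so LOOCV must agree with the oracle point for point
    X1 <- data.frame(f1 = rnorm(n))
    res1 <- loocv(classifier_spec("knn", k = 1), X1, y)
    expect_equal(res1$pred, as.integer(brute_1nn_loocv(as.matrix(X1), y)))
  }
})

test_that("LOOCV predictions are invariant to row order", {
  b <- make_blobs(n_per = 8, sep = 3, seed = 4)
  for (spec in list(classifier_spec("knn", k = 3),
                    classifier_spec("discriminant"))) {
    res <- loocv(spec, b$X, b$y)
    set.seed(5)
    perm <- sample(length(b$y))
    res_p <- loocv(spec, b$X[perm, ], b$y[perm])
    expect_equal(res_p$pred, res$pred[perm], info = spec$family)
  }
})

test_that("singleton-class folds are allowed and logged", {
  set.seed(6)
  X <- data.frame(f1 = c(rnorm(5), rnorm(5, 8), 20), f2 = rnorm(11))
  y <- c(rep(0L, 5), rep(1L, 5), 4L)
  res <- loocv(classifier_spec("decision_tree"), X, y)
  expect_equal(res$missing_class_folds, 11L)
  expect_true(res$pred[11] %in% c(0L, 1L)) # class 4 unseen in its fold
})

test_that("fold-internal selection keeps the held-out row out of the fit", {
  set.seed(7)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("f", 1:6)
  y <- rep(c(0L, 1L), each = n / 2)
  X$f1 <- X$f1 + 3 * y # one informative feature
  for (m in c("pairwise", "pca")) {
    res <- loocv(classifier_spec("knn", k = 3), X, y,
                 selection = list(method = m, d = 2))
    expect_length(res$pred, n)
    expect_true(all(res$pred %in% 0:1))
  }
  # fit_on_all variant runs and is deterministic
  r1 <- loocv(classifier_spec("knn", k = 3), X, y,
              selection = list(method = "pairwise", d = 2, fit_on_all = TRUE))
  r2 <- loocv(classifier_spec("knn", k = 3), X, y,
              selection = list(method = "pairwise", d = 2, fit_on_all = TRUE))
  expect_identical(r1$pred, r2$pred)
})

test_that("grid search ranks feature counts by accuracy reproducibly", {
  set.seed(8)
  n <- 24
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(X) <- paste0("f", 1:5)
  y <- rep(c(0L, 1L, 2L), each = n / 3)
  X$f2 <- X$f2 + y
  gs <- grid_search(list(classifier_spec("knn", k = 3)), X, y,
                    d_values = c(1, 2))
  expect_equal(nrow(gs$all), 2)
  expect_equal(nrow(gs$best), 1)
  expect_equal(gs$best$accuracy, max(gs$all$accuracy))
  gs2 <- grid_search(list(classifier_spec("knn", k = 3)), X, y,
                     d_values = c(1, 2))
  expect_identical(gs$all, gs2$all)
})

test_that("classifier specifications validate their arguments", {
  expect_error(classifier_spec("knn", k = 4), "odd")
  expect_error(classifier_spec("boosting"), "arg")
  expect_silent(classifier_spec("svm", kernel = "polynomial"))
  expect_error(fit_classifier(classifier_spec("knn"),
                              data.frame(f1 = c(1, NA)), c(0L, 1L)), "finite")
})
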