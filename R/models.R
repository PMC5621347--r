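#' Specify a classifier
#'
#' The five classifier families compared for automatic severity scoring:
#' decision tree (Gini impurity, unpruned, minimum leaf size 1), support
#' vector machine (linear, polynomial degree 3, or RBF kernel; cost 1),
#' linear discriminant analysis (quadratic available), random forest
#' (100 trees, seeded), and k-nearest neighbours (Euclidean metric,
#' uniform votes, odd k between 1 and 11, deterministic lower-label
#' tie-breaks). Scale-sensitive families (svm, knn, discriminant) are
#' z-scored inside each training fold; trees and forests consume raw
#' features.
#'
#' @param family one of `"decision_tree"`, `"svm"`, `"discriminant"`,
#'   `"random_forest"`, `"knn"`.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` or `"rbf"`.
#' @param k number of neighbours for kNN; odd, in 1-11.
#' @param seed seed for stochastic families (random forest).
#' @param cost,degree SVM hyperparameters.
#' @param ntree random-forest size.
#' @param discriminant_type `"lda"` or `"qda"`.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("decision_tree", "svm", "discriminant",
                                       "random_forest", "knn"),
                            kernel = c("rbf", "linear", "polynomial"),
                            k = 3, seed = 1, cost = 1, degree = 3,
                            ntree = 100, discriminant_type = c("lda", "qda")) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  discriminant_type <- match.arg(discriminant_type)
  if (family == "knn") {
    if (!k %in% c(1, 3, 5, 7, 9, 11)) stop("k must be odd, between 1 and 11")
  }
  structure(list(family = family, kernel = kernel, k = as.integer(k),
                 seed = as.integer(seed), cost = cost, degree = degree,
                 ntree = as.integer(ntree),
                 discriminant_type = discriminant_type),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$family,
                  svm = paste0(" (", x$kernel, ")"),
                  knn = paste0(" (k=", x$k, ")"),
                  discriminant = paste0(" (", x$discriminant_type, ")"),
                  "")
  cat("<classifier_spec> ", x$family, extra, "\n", sep = "")
  invisible(x)
}

scale_sensitive <- function(spec) {
  spec$family %in% c("svm", "knn", "discriminant")
}

# z-score training columns; zero-variance columns pass through unscaled
fold_scaler <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  list(center = ctr, scale = sds)
}

apply_scaler <- function(X, sc) {
  scale(X, center = sc$center, scale = sc$scale)
}

#' Fit a classifier on a training set
#'
#' @param spec a [classifier_spec()].
#' @param X data frame or matrix of numeric features.
#' @param y integer class labels 0-4.
#' @return a fitted model object usable with [predict_classifier()].
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(as.data.frame(X))
  if (!all(is.finite(X))) stop("features must be finite")
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% 0:4))
  classes <- sort(unique(y))
  if (length(classes) == 1) {
    return(structure(list(spec = spec, constant = classes), class = "tremor_fit"))
  }
  sc <- NULL
  if (scale_sensitive(spec)) {
    sc <- fold_scaler(X)
    X <- apply_scaler(X, sc)
  }
  yf <- factor(y, levels = classes)
  fit <- switch(
    spec$family,
    decision_tree = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                  cp = 0, xval = 0))
    },
    svm = {
      gam <- 1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), .Machine$double.eps))
      e1071::svm(X, yf, scale = FALSE,
                 kernel = switch(spec$kernel, rbf = "radial", spec$kernel),
                 cost = spec$cost, degree = spec$degree, gamma = gam)
    },
    discriminant = {
      if (spec$discriminant_type == "lda") MASS::lda(X, grouping = yf)
      else MASS::qda(X, grouping = yf)
    },
    random_forest = {
      set.seed(spec$seed)
      randomForest::randomForest(X, yf, ntree = spec$ntree)
    },
    knn = list(X = X, y = y) # lazy learner: store the training set
  )
  structure(list(spec = spec, fit = fit, scaler = sc,
                 columns = colnames(X)), class = "tremor_fit")
}

# Euclidean kNN with deterministic tie-breaks: among equidistant training
# points the lower class label ranks first, and vote ties go to the lower
# label.
knn_predict_one <- function(trainX, trainy, x, k) {
  d2 <- colSums((t(trainX) - x)^2)
  o <- order(d2, trainy)
  votes <- trainy[o[seq_len(min(k, length(o)))]]
  tab <- table(votes)
  as.integer(names(tab)[which.max(tab)]) # first max = lowest label
}

#' Predict classes for new rows
#'
#' @param model a [fit_classifier()] result.
#' @param X data frame or matrix of feature rows.
#' @return integer vector of predicted classes 0-4.
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "tremor_fit"))
  X <- as.matrix(as.data.frame(X))
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  if (!is.null(model$scaler)) X <- apply_scaler(X, model$scaler)
  spec <- model$spec
  out <- switch(
    spec$family,
    decision_tree = {
      cls <- predict(model$fit, newdata = as.data.frame(X, check.names = FALSE),
                     type = "class")
      as.integer(as.character(cls))
    },
    svm = as.integer(as.character(predict(model$fit, X))),
    discriminant = as.integer(as.character(predict(model$fit, X)$class)),
    random_forest = as.integer(as.character(predict(model$fit, X))),
    knn = vapply(seq_len(nrow(X)), function(i) {
      knn_predict_one(model$fit$X, model$fit$y, X[i, ], spec$k)
    }, integer(1))
  )
  out
}

resolve_fold_features <- function(Xtr, Xte, selection) {
  if (is.null(selection) || selection$method == "none") {
    return(list(train = Xtr, test = Xte))
  }
  if (selection$method == "pairwise") {
    ord <- suppressWarnings(
      pairwise_order(Xtr, extension = selection$extension %||% "minimax"))
    d <- min(selection$d, length(ord$order))
    feats <- select_top(ord, d)
    list(train = Xtr[feats], test = Xte[feats])
  } else if (selection$method == "pca") {
    fit <- pca_fit(Xtr, selection$d)
    list(train = as.data.frame(fit$scores),
         test = as.data.frame(predict(fit, Xte)))
  } else {
    stop("unknown selection method: ", selection$method)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out cross-validation
#'
#' Each recording is predicted by a model trained on all others. When a
#' selection configuration is given, feature ordering or the PCA basis is
#' refit inside each training fold by default, so the held-out row never
#' influences the feature configuration it is scored with
#' (`fit_on_all = TRUE` reproduces the optimistic variant that fits
#' selection on the full data once). A training fold may lack a class
#' entirely (a singleton class's own fold); this is allowed and noted in
#' the result.
#'
#' @param spec a [classifier_spec()].
#' @param X data frame of features (a `label` column is dropped).
#' @param y integer labels 0-4.
#' @param selection `NULL`, or a list with `method` (`"pairwise"` or
#'   `"pca"`), `d` (number of features / components), optional `extension`
#'   and `fit_on_all`.
#' @return An object of class `loocv_result`: list with `truth`, `pred`
#'   (integer vectors), `spec`, `selection`, and `missing_class_folds`.
#' @export
loocv <- function(spec, X, y, selection = NULL) {
  X <- as.data.frame(X)
  X$label <- NULL
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  if (!is.null(selection) && isTRUE(selection$fit_on_all)) {
    pre <- resolve_fold_features(X, X, selection)
    X <- pre$train
    selection <- NULL
  }
  missing_folds <- integer(0)
  pred <- integer(n)
  for (i in seq_len(n)) {
    fold <- resolve_fold_features(X[-i, , drop = FALSE],
                                  X[i, , drop = FALSE], selection)
    if (!y[i] %in% y[-i]) missing_folds <- c(missing_folds, i)
    model <- fit_classifier(spec, fold$train, y[-i])
    pred[i] <- predict_classifier(model, fold$test)
  }
  structure(list(truth = y, pred = pred, spec = spec, selection = selection,
                 missing_class_folds = missing_folds),
            class = "loocv_result")
}

#' LOOCV accuracy
#' @param result a [loocv()] result.
#' @return fraction of correct predictions.
#' @export
loocv_accuracy <- function(result) {
  stopifnot(inherits(result, "loocv_result"))
  mean(result$pred == result$truth)
}

#' Search classifier and feature-count grids by LOOCV accuracy
#'
#' Runs [loocv()] for every combination of classifier specification and
#' feature count, and reports the accuracy-maximizing count per
#' classifier, ranked by accuracy.
#'
#' @param specs list of [classifier_spec()] objects.
#' @param X data frame of features.
#' @param y integer labels 0-4.
#' @param d_values feature counts (pairwise prefix lengths or PCA
#'   component counts) to try.
#' @param method `"pairwise"` or `"pca"`.
#' @param extension,fit_on_all passed through to the selection
#'   configuration, see [loocv()].
#' @return list with `all` (one row per spec x d) and `best` (the
#'   maximizing d per spec, ranked by accuracy; ties prefer smaller d).
#' @export
grid_search <- function(specs, X, y, d_values, method = "pairwise",
                        extension = "minimax", fit_on_all = FALSE) {
  stopifnot(length(specs) > 0, length(d_values) > 0)
  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (d in d_values) {
      res <- loocv(spec, X, y,
                   selection = list(method = method, d = d,
                                    extension = extension,
                                    fit_on_all = fit_on_all))
      rows[[length(rows) + 1]] <- data.frame(
        spec_index = si, family = spec$family,
        kernel = if (spec$family == "svm") spec$kernel else NA_character_,
        k = if (spec$family == "knn") spec$k else NA_integer_,
        d = d, accuracy = loocv_accuracy(res))
    }
  }
  all <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(all, all$spec_index), function(g) {
    g <- g[order(-g$accuracy, g$d), ]
    g[1, ]
  }))
  best <- best[order(-best$accuracy, best$d), ]
  rownames(best) <- NULL
  list(all = all, best = best)
}
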