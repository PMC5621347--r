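#' Order features by pairwise decorrelation
#'
#' Greedy "most unrelated first" ordering. All pairwise Pearson
#' correlations are computed in absolute value (a correlation of -0.9 is
#' as redundant as +0.9); the first two features are the pair with the
#' minimum `|r|`, and each subsequent feature is the one whose largest
#' `|r|` against the already-selected set is smallest (minimax extension;
#' a mean-`|r|` extension is available). Ties break on canonical column
#' order, so the ordering is deterministic. Constant features have no
#' defined correlation and are excluded with a warning.
#'
#' @param X data frame or matrix of features (no label column).
#' @param extension `"minimax"` (default) or `"mean"`: criterion scoring a
#'   candidate against the selected set.
#' @return An object of class `selection_order`: list with `order`
#'   (feature names, most unrelated first) and `trace` (the `|r|` score at
#'   which each feature entered; `NA` for the first).
#' @export
pairwise_order <- function(X, extension = c("minimax", "mean")) {
  extension <- match.arg(extension)
  X <- as.data.frame(X)
  X$label <- NULL
  if (ncol(X) < 2) stop("need at least 2 features")
  if (nrow(X) < 3) stop("need at least 3 samples")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("excluding constant feature(s): ",
            paste(names(X)[sds == 0], collapse = ", "))
    X <- X[sds > 0]
    if (ncol(X) < 2) stop("fewer than 2 usable (non-constant) features")
  }
  r <- abs(stats::cor(as.matrix(X)))
  nm <- colnames(r)
  p <- ncol(r)

  # seed with the least correlated pair; which() scans column-major so the
  # first hit is the canonical tie-break
  off <- r
  diag(off) <- Inf
  seed <- which(off == min(off), arr.ind = TRUE)[1, ]
  sel <- sort(seed) # canonical order within the pair
  trace <- c(NA_real_, off[seed[1], seed[2]])

  while (length(sel) < p) {
    rest <- setdiff(seq_len(p), sel)
    score <- vapply(rest, function(j) {
      v <- r[j, sel]
      if (extension == "minimax") max(v) else mean(v)
    }, numeric(1))
    pick <- rest[which.min(score)]
    trace <- c(trace, min(score))
    sel <- c(sel, pick)
  }
  structure(list(order = nm[sel], trace = trace), class = "selection_order")
}

#' First d features of a selection order
#' @param order a [pairwise_order()] result.
#' @param d number of features to keep, `1 <= d <= length(order$order)`.
#' @return character vector of `d` feature names (prefix of the order).
#' @export
select_top <- function(order, d) {
  stopifnot(inherits(order, "selection_order"))
  if (d < 1 || d > length(order$order)) {
    stop("d must be between 1 and ", length(order$order))
  }
  order$order[seq_len(d)]
}

#' Fit a standardized principal component projection
#'
#' Features are z-scored before decomposition: the 76 features span
#' incommensurate units (seconds, metres, log-power), and unstandardized
#' PCA would be dominated by whichever unit is numerically largest.
#'
#' @param X data frame or matrix of features (no label column).
#' @param n_components number of components to retain.
#' @return An object of class `tremor_pca`: list with `rotation` (loadings),
#'   `center`, `scale`, `explained` (variance fractions, non-increasing),
#'   and `scores` (projection of the training data).
#' @export
pca_fit <- function(X, n_components) {
  X <- as.data.frame(X)
  X$label <- NULL
  if (n_components < 1 || n_components > min(nrow(X), ncol(X))) {
    stop("n_components must be in 1..", min(nrow(X), ncol(X)))
  }
  sds <- vapply(X, stats::sd, numeric(1))
  scale_vec <- ifelse(sds > 0, sds, 1) # constant columns carry no variance
  pc <- stats::prcomp(as.matrix(X), center = TRUE, scale. = scale_vec)
  k <- seq_len(n_components)
  structure(
    list(rotation = pc$rotation[, k, drop = FALSE],
         center = pc$center, scale = pc$scale,
         explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
         scores = pc$x[, k, drop = FALSE]),
    class = "tremor_pca"
  )
}

#' Project new rows onto a fitted principal component basis
#' @param object a [pca_fit()] result.
#' @param newdata data frame or matrix with the training feature columns.
#' @param ... unused.
#' @return matrix of projected coordinates.
#' @export
predict.tremor_pca <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  newdata$label <- NULL
  m <- as.matrix(newdata[rownames(object$rotation)])
  scale(m, center = object$center, scale = object$scale) %*% object$rotation
}
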