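#' Fit an RBF-kernel support vector regression
#'
#' Thin wrapper around [e1071::svm()] holding the hyperparameter policy used
#' by every SVR in the package: features standardised to zero mean / unit
#' variance inside the wrapper (parameters stored), RBF kernel width from the
#' median-pairwise-distance heuristic on the standardised training features
#' (`gamma = 1 / (2 * median^2)`), regularisation cost 1, epsilon tube
#' `0.1 * sd(y)`. Degenerate inputs (single training point, constant labels)
#' fall back to a constant predictor at the label mean.
#'
#' @param x Numeric matrix of training features (cells x genes).
#' @param y Numeric label vector (AUC).
#' @param cost Regularisation weight.
#' @param gamma RBF width; `NULL` = median heuristic.
#' @param epsilon Epsilon tube; `NULL` = `0.1 * sd(y)`.
#' @return Object of class `kesvr_svr`.
#' @export
fit_svr <- function(x, y, cost = 1, gamma = NULL, epsilon = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(y)))
  feats <- colnames(x)
  if (nrow(x) < 2L || stats::sd(y) == 0) {
    return(structure(list(type = "constant", value = mean(y), features = feats),
                     class = "kesvr_svr"))
  }
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  if (is.null(gamma)) {
    m <- stats::median(stats::dist(xs))
    gamma <- if (is.finite(m) && m > 0) 1 / (2 * m^2) else 1 / ncol(x)
  }
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(y)
  fit <- e1071::svm(x = xs, y = y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  structure(list(type = "svm", fit = fit, center = center, scale = scale,
                 gamma = gamma, cost = cost, epsilon = epsilon,
                 features = feats),
            class = "kesvr_svr")
}

#' Predict from a fitted SVR wrapper
#'
#' @param object A `kesvr_svr`.
#' @param newdata Feature matrix (cells x genes) or a single feature vector.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.kesvr_svr <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (ncol(newdata) != length(object$features))
      stop_kesvr("feature dimension mismatch: model expects ",
                 length(object$features), " genes, got ", ncol(newdata))
    if (!is.null(colnames(newdata)) &&
        !identical(colnames(newdata), object$features))
      newdata <- newdata[, object$features, drop = FALSE]
  }
  if (object$type == "constant")
    return(stats::setNames(rep(object$value, nrow(newdata)), rownames(newdata)))
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  p <- as.numeric(stats::predict(object$fit, xs))
  stats::setNames(p, rownames(newdata))
}
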