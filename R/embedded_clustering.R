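#' Assemble the labeled dataset Q
#'
#' Pairs each aligned cell line's target-gene expression with its AUC label.
#' All SVRs in the package train on these features, while the PCA embedding
#' uses the full gene set; the two feature spaces are deliberately
#' independent.
#'
#' @param expr Aligned expression matrix (all genes).
#' @param resp Aligned `kesvr_response`.
#' @param genes Target-gene subset (character vector, present in `expr`).
#' @return Object of class `kesvr_labeled`: list with `features` (cells x
#'   genes matrix) and `labels` (named numeric AUC).
#' @export
labeled_data <- function(expr, resp, genes) {
  stopifnot(all(genes %in% rownames(expr)),
            identical(colnames(expr), names(resp$auc)))
  structure(list(features = t(expr[genes, , drop = FALSE]),
                 labels = resp$auc),
            class = "kesvr_labeled")
}

#' Train the global SVR on a seeded 75/25 split
#'
#' Fits the single support vector regression S on a seeded random fraction
#' (default 75\%) of the labeled data; the split membership is recorded so
#' every downstream step is reproducible.
#'
#' @param q A `kesvr_labeled`.
#' @param train_fraction Fraction of cells used for training.
#' @param seed Integer seed driving the split.
#' @return List with `model` (a `kesvr_svr`) and `split` (list of `train` /
#'   `test` cell ids, plus the seed and fraction used).
#' @export
train_global_svr <- function(q, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(q, "kesvr_labeled"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(q$features)
  if (n < 3L) stop_kesvr("need at least 3 cells to split for the global SVR")
  idx <- split_indices(n, train_fraction, seed)
  cells <- rownames(q$features)
  model <- fit_svr(q$features[idx$train, , drop = FALSE], q$labels[idx$train])
  list(model = model,
       split = list(train = cells[idx$train], test = cells[idx$test],
                    seed = seed, fraction = train_fraction))
}

#' Residuals of the global SVR over all cell lines
#'
#' Signed prediction errors e_i = Y_i - S(X_i) for every aligned cell line
#' (training and held-out alike), forming the residual dataset that k-means
#' partitions.
#'
#' @param s A fitted `kesvr_svr` (the global model).
#' @param q The `kesvr_labeled` it was trained on.
#' @param absolute Use absolute residuals instead of signed ones.
#' @return Data frame of class `kesvr_residuals` with columns `cell`, `auc`,
#'   `error`.
#' @export
compute_residuals <- function(s, q, absolute = FALSE) {
  stopifnot(inherits(s, "kesvr_svr"), inherits(q, "kesvr_labeled"))
  pred <- predict(s, q$features)
  e <- unname(q$labels) - unname(pred)
  if (absolute) e <- abs(e)
  structure(data.frame(cell = rownames(q$features), auc = unname(q$labels),
                       error = e, stringsAsFactors = FALSE),
            class = c("kesvr_residuals", "data.frame"))
}

# Seeded k-means++ center initialisation (distinct data points, D^2 sampling).
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2L:K) {
      if (sum(d2) <= 0) return(NULL)            # fewer distinct points than K
      i <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' K-means partition of the residual dataset
#'
#' Standard Euclidean k-means in the raw (AUC, error) plane — both axes are
#' in AUC units, so no standardisation is applied. Each of `restarts`
#' restarts draws seeded k-means++ centers and is finished by Lloyd
#' iterations; the converged partition with the lowest within-cluster sum of
#' squares is kept. Restarts that produce an empty cluster are discarded; if
#' every restart does, the requested K is infeasible and `NULL` is returned
#' (the k-loop skips it).
#'
#' Clusters are relabeled in ascending order of centroid AUC so that labels,
#' and the deterministic tie-breaks that reference them, are reproducible.
#'
#' @param psi A `kesvr_residuals`.
#' @param K Number of clusters (1 <= K <= number of cells).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (>= 10 recommended).
#' @return Object of class `kesvr_partition` (fields `k`, `labels` — named
#'   integer vector —, `centroids`, `sizes`, `tot_withinss`), or `NULL` if K
#'   is infeasible.
#' @export
cluster_residuals <- function(psi, K, seed = 1L, restarts = 10L) {
  stopifnot(inherits(psi, "kesvr_residuals"))
  n <- nrow(psi)
  K <- as.integer(K)
  if (K < 1L) stop_kesvr("K must be >= 1")
  if (K > n) stop_kesvr("K = ", K, " exceeds the number of cells (", n, ")")
  X <- cbind(auc = psi$auc, error = psi$error)
  if (K == 1L) {
    labels <- stats::setNames(rep(1L, n), psi$cell)
    cen <- matrix(colMeans(X), 1L, 2L, dimnames = list(NULL, colnames(X)))
    return(structure(list(k = 1L, labels = labels, centroids = cen,
                          sizes = n, tot_withinss = sum(sweep(X, 2L, cen[1L, ])^2)),
                     class = "kesvr_partition"))
  }
  if (nrow(unique(X)) < K) return(NULL)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- with_seed(seed + r - 1L, kmeanspp_centers(X, K))
    if (is.null(centers)) next
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0L)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) return(NULL)
  ord <- order(best$centers[, 1L])                 # ascending centroid AUC
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  labels <- stats::setNames(relabel[best$cluster], psi$cell)
  structure(list(k = K, labels = labels,
                 centroids = best$centers[ord, , drop = FALSE],
                 sizes = as.integer(tabulate(labels, K)),
                 tot_withinss = best$tot.withinss),
            class = "kesvr_partition")
}

#' Transfer the residual-plane partition onto the reduced dataset Z
#'
#' Pure relabeling keyed by cell id: cell i carries the same cluster label in
#' Z as in the residual dataset; nothing is recomputed.
#'
#' @param z A `kesvr_reduced`.
#' @param part A `kesvr_partition` over the same cell ids.
#' @return `z` with an added integer `cluster` column.
#' @export
transfer_partition <- function(z, part) {
  stopifnot(inherits(z, "kesvr_reduced"), inherits(part, "kesvr_partition"))
  if (!setequal(z$cell, names(part$labels)))
    stop_kesvr("cell ids of the reduced dataset and the partition differ")
  z$cluster <- unname(part$labels[z$cell])
  z
}
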