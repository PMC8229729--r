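#' Mean squared error and the average train+test MSE
#'
#' `mse()` is the plain mean of squared differences; `avg_mse()` is the
#' model-scoring metric used throughout the package: the mean of the MSE on
#' the training split and the MSE on the testing split.
#'
#' @param y_true,y_pred Numeric vectors of equal, positive length.
#' @param train_mse,test_mse Scalar MSEs of the two splits.
#' @return Scalar.
#' @export
mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  mean((y_true - y_pred)^2)
}

#' @rdname mse
#' @export
avg_mse <- function(train_mse, test_mse) (train_mse + test_mse) / 2

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of `y_true`; may be negative for fits worse than the mean predictor.
#'
#' @param y_true Observed values (not constant, length >= 2).
#' @param y_pred Predicted values.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop_kesvr("R squared undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Select the optimal cluster count from a per-k MSE table
#'
#' Returns the feasible k with the lowest average (training + testing) MSE;
#' ties go to the smaller k.
#'
#' @param mse_table Data frame with columns `k`, `avg_mse` and optionally
#'   `feasible` (logical; missing = all feasible).
#' @return The selected integer k.
#' @export
select_optimal_k <- function(mse_table) {
  stopifnot(is.data.frame(mse_table), all(c("k", "avg_mse") %in% names(mse_table)))
  feas <- if ("feasible" %in% names(mse_table)) mse_table$feasible else
    rep(TRUE, nrow(mse_table))
  feas <- feas & is.finite(mse_table$avg_mse)
  if (!any(feas)) stop_kesvr("no feasible cluster count")
  cand <- mse_table[feas, , drop = FALSE]
  cand <- cand[order(cand$avg_mse, cand$k), , drop = FALSE]
  as.integer(cand$k[1L])
}

# Ensemble predictions for a batch of inputs against fixed per-k artifacts.
# `sp_mat` holds Spearman correlations: training cells (rows, in zc order) x
# inputs (columns). Returns list(psi, traces).
ensemble_predict_batch <- function(ids, cand_mat, phi, zc, ladder, sp_mat,
                                   global_values) {
  traces <- vector("list", length(ids))
  psi <- numeric(length(ids))
  for (i in seq_along(ids)) {
    tr <- select_prediction_impl(ids[i], cand_mat[i, ], phi[i], zc, ladder,
                                 sp_mat[, i], global_values[i])
    traces[[i]] <- tr
    psi[i] <- tr$psi
  }
  names(psi) <- ids
  list(psi = psi, traces = traces)
}

# Flatten a list of prediction traces into a long data frame for export.
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    df <- tr$candidates
    df$input <- tr$id
    df$radius <- tr$radius
    df$selected <- !tr$fallback & df$cluster == tr$cluster
    df$psi <- tr$psi
    df$fallback <- tr$fallback
    df[, c("input", "cluster", "value", "n_neighbors", "beta", "radius",
           "selected", "psi", "fallback")]
  }))
}

#' Fit a kESVR model for one drug
#'
#' Runs the full pipeline: PCA embedding of the full gene set, global RBF
#' SVR on the target genes (seeded 75/25 split), signed residuals over all
#' cells, and then for each k in `1..k_max`: a k-means partition of the
#' residual plane, one local SVR per cluster (per-cluster 75/25 splits), and
#' ensemble-selected predictions for every cell. Each k is scored by the
#' average of the MSE over the union of the per-cluster training splits and
#' the MSE over the union of the testing splits; the model with the lowest
#' score is retained together with the full per-k table.
#'
#' @param expr Expression matrix, genes x cells.
#' @param resp A `kesvr_response` for the modeled drug.
#' @param genes Optional target-gene subset (default: all genes).
#' @param k_max Largest cluster count tried (default 12).
#' @param train_fraction Training fraction for every split.
#' @param seed Integer seed driving every split and k-means restart; the
#'   same seed drives every k so the k-loop compares models, not split luck.
#' @param p Principal-component override (default: component 1).
#' @param restarts K-means restarts per k.
#' @return Object of class `kesvr_model`.
#' @export
fit_kesvr <- function(expr, resp, genes = NULL, k_max = 12L,
                      train_fraction = 0.75, seed = 1L, p = NULL,
                      restarts = 10L) {
  stopifnot(k_max >= 1L)
  al <- align_inputs(expr, resp, genes)
  emb <- fit_pca(al$expr)
  p <- select_component(emb, p)
  z <- build_reduced_dataset(emb, al$expr, al$resp, p)
  q <- labeled_data(al$expr, al$resp, al$genes)
  cells <- rownames(q$features)

  global <- train_global_svr(q, train_fraction, seed)
  psi_res <- compute_residuals(global$model, q)
  global_pred <- predict(global$model, q$features)

  # Spearman correlations between all pairs of training cells, reused by
  # every k (they do not depend on the partition).
  rn <- rank_normalize_rows(q$features)
  sp_mat <- tcrossprod(rn)            # cells x cells, rows/cols in q order

  tab <- data.frame(k = seq_len(k_max), train_mse = NA_real_,
                    test_mse = NA_real_, avg_mse = NA_real_,
                    feasible = FALSE)
  best <- NULL
  for (k in seq_len(k_max)) {
    part <- cluster_residuals(psi_res, k, seed, restarts)
    if (is.null(part)) next
    zc <- transfer_partition(z, part)
    locals <- train_local_svrs(q, part, train_fraction, seed)
    ladder <- compute_radius_ladder(zc)
    cand <- predict_candidates(locals, q$features)
    batch <- ensemble_predict_batch(cells, cand, z$pc, zc, ladder,
                                    t(sp_mat), global_pred)
    train_ids <- unlist(lapply(locals$clusters, `[[`, "train"))
    test_ids <- unlist(lapply(locals$clusters, `[[`, "test"))
    m_train <- mse(q$labels[train_ids], batch$psi[train_ids])
    m_test <- if (length(test_ids)) mse(q$labels[test_ids], batch$psi[test_ids])
              else NA_real_
    m_avg <- if (is.na(m_test)) m_train else avg_mse(m_train, m_test)
    tab[k, c("train_mse", "test_mse", "avg_mse")] <- c(m_train, m_test, m_avg)
    tab$feasible[k] <- TRUE
    if (is.null(best) || m_avg < best$avg_mse)
      best <- list(k = k, partition = part, locals = locals, ladder = ladder,
                   z = zc, psi = batch$psi, traces = batch$traces,
                   train_ids = train_ids, test_ids = test_ids,
                   avg_mse = m_avg)
  }
  if (is.null(best)) stop_kesvr("every cluster count 1..", k_max, " was infeasible")
  optimal_k <- select_optimal_k(tab)
  stopifnot(identical(optimal_k, best$k))

  structure(list(
    drug = al$resp$drug,
    cells = cells,
    genes = al$genes,
    gene_universe = rownames(al$expr),
    p = p,
    pca_center = emb$center,
    pca_loading = emb$loadings[, p],
    var_explained = emb$var_explained,
    global_svr = global$model,
    global_split = global$split,
    residuals = psi_res,
    partition = best$partition,
    local_models = best$locals,
    ladder = best$ladder,
    z = best$z,
    train_features = q$features,
    train_labels = q$labels,
    rank_norm = rn,
    psi_in_sample = best$psi,
    traces_in_sample = best$traces,
    train_ids = best$train_ids,
    test_ids = best$test_ids,
    optimal_k = optimal_k,
    mse_table = tab,
    seed = seed,
    train_fraction = train_fraction,
    k_max = as.integer(k_max)),
    class = "kesvr_model")
}

#' @export
print.kesvr_model <- function(x, ...) {
  cat("kESVR model for drug '", x$drug, "'\n", sep = "")
  cat("  cells: ", length(x$cells), ", target genes: ", length(x$genes),
      ", principal component: ", x$p, "\n", sep = "")
  cat("  optimal k: ", x$optimal_k, " (searched 1..", x$k_max, ")\n", sep = "")
  cat("  avg (train+test) MSE at optimal k: ",
      format(x$mse_table$avg_mse[x$optimal_k], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict drug response with a fitted kESVR model
#'
#' Projects each input onto the stored principal component, collects one
#' candidate per local SVR, and arbitrates by the neighbourhood-averaged
#' Spearman score against the stored training geometry. Fully deterministic.
#'
#' @param object A `kesvr_model`.
#' @param expr_new Expression matrix containing every training gene.
#' @param r_override Optional fixed radius replacing the ladder (the
#'   global-SVR fallback still applies if every neighbourhood is empty).
#' @param trace Return per-candidate traces alongside the predictions.
#' @param ... Unused.
#' @return Named numeric vector of predicted AUC values, or, with
#'   `trace = TRUE`, a list with `psi` and a long-format `trace` data frame.
#' @export
predict.kesvr_model <- function(object, expr_new, r_override = NULL,
                                trace = FALSE, ...) {
  stopifnot(is.matrix(expr_new))
  if (ncol(expr_new) == 0L) stop_kesvr("empty input expression matrix")
  missing <- setdiff(object$gene_universe, rownames(expr_new))
  if (length(missing))
    stop_kesvr("input lacks ", length(missing), " model gene(s): ",
               paste(utils::head(missing, 10L), collapse = ", "),
               if (length(missing) > 10L) ", ...")
  ids <- colnames(expr_new)
  centred <- expr_new[names(object$pca_center), , drop = FALSE] - object$pca_center
  phi <- drop(crossprod(centred, object$pca_loading))
  feats <- t(expr_new[object$genes, , drop = FALSE])
  cand <- predict_candidates(object$local_models, feats)
  global_values <- predict(object$global_svr, feats)
  xn <- rank_normalize_rows(feats)
  # rank_norm rows follow q order == zc order (both the aligned cell order)
  sp_mat <- object$rank_norm %*% t(xn)
  ladder <- if (is.null(r_override)) object$ladder else
    structure(list(spans = r_override, r = r_override), class = "kesvr_ladder")
  batch <- ensemble_predict_batch(ids, cand, phi, object$z, ladder, sp_mat,
                                  global_values)
  if (!trace) return(batch$psi)
  list(psi = batch$psi, trace = traces_to_df(batch$traces))
}

#' Seeded k-fold cross-validation of kESVR and its baselines
#'
#' Assigns the aligned cells to `folds` balanced folds (seeded), fits the
#' chosen method on the training portion of each fold and evaluates on the
#' held-out portion. The per-fold score is the average of the training-
#' portion MSE and the held-out MSE; the overall score is the mean of the
#' per-fold averages. With `iterations > 1` the whole procedure is repeated
#' with fresh fold assignments (seeds `seed`, `seed + 1`, ...) and all fold
#' rows are pooled. RMSE is reported as the square root of each fold's
#' held-out MSE, averaged over folds; R squared is computed on the held-out
#' predictions pooled within each iteration, then averaged.
#'
#' @param expr,resp,genes As in [fit_kesvr()].
#' @param folds Number of folds (>= 2, default 5).
#' @param iterations Number of repeats (default 1).
#' @param seed Integer seed.
#' @param k_max,train_fraction,restarts Passed to [fit_kesvr()].
#' @param method `"kesvr"`, `"svr"` or `"linear"`.
#' @return Object of class `kesvr_report`: list with `folds` (one row per
#'   iteration x fold), `avg_mse`, `rmse`, `r_squared`, `method`,
#'   `assignments`.
#' @export
cross_validate <- function(expr, resp, genes = NULL, folds = 5L,
                           iterations = 1L, seed = 1L, k_max = 12L,
                           train_fraction = 0.75, restarts = 10L,
                           method = c("kesvr", "svr", "linear")) {
  method <- match.arg(method)
  stopifnot(folds >= 2L, iterations >= 1L)
  al <- align_inputs(expr, resp, genes)
  cells <- colnames(al$expr)
  n <- length(cells)
  if (folds > n) stop_kesvr("more folds (", folds, ") than cells (", n, ")")
  rows <- list(); assignments <- list(); r2 <- numeric(iterations)
  for (it in seq_len(iterations)) {
    fold_of <- with_seed(seed + it - 1L, sample(rep_len(seq_len(folds), n)))
    names(fold_of) <- cells
    assignments[[it]] <- fold_of
    pooled_pred <- stats::setNames(numeric(n), cells)
    for (f in seq_len(folds)) {
      train_cells <- cells[fold_of != f]
      test_cells <- cells[fold_of == f]
      fit <- fit_method(method, al$expr[, train_cells, drop = FALSE],
                        response_vector(al$resp$drug, al$resp$auc[train_cells]),
                        al$genes, k_max, train_fraction, seed, restarts)
      pred_train <- fit$predict(al$expr[, train_cells, drop = FALSE])
      pred_test <- fit$predict(al$expr[, test_cells, drop = FALSE])
      m_train <- mse(al$resp$auc[train_cells], pred_train[train_cells])
      m_test <- mse(al$resp$auc[test_cells], pred_test[test_cells])
      pooled_pred[test_cells] <- pred_test[test_cells]
      rows[[length(rows) + 1L]] <-
        data.frame(iteration = it, fold = f, n_train = length(train_cells),
                   n_test = length(test_cells), train_mse = m_train,
                   test_mse = m_test, avg_mse = avg_mse(m_train, m_test))
    }
    r2[it] <- r_squared(al$resp$auc[cells], pooled_pred[cells])
  }
  fold_df <- do.call(rbind, rows)
  structure(list(method = method,
                 folds = fold_df,
                 avg_mse = mean(fold_df$avg_mse),
                 rmse = mean(sqrt(fold_df$test_mse)),
                 r_squared = mean(r2),
                 assignments = assignments),
            class = "kesvr_report")
}

#' @export
print.kesvr_report <- function(x, ...) {
  cat("Cross-validation report (", x$method, ")\n", sep = "")
  print(x$folds, row.names = FALSE)
  cat("overall avg (train+test) MSE: ", format(x$avg_mse, digits = 4),
      "; RMSE: ", format(x$rmse, digits = 4),
      "; R squared: ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

# Uniform fit interface for cross_validate: returns list(predict = function).
fit_method <- function(method, expr, resp, genes, k_max, train_fraction,
                       seed, restarts) {
  if (method == "kesvr") {
    m <- fit_kesvr(expr, resp, genes, k_max = k_max,
                   train_fraction = train_fraction, seed = seed,
                   restarts = restarts)
    list(predict = function(e) predict(m, e), model = m)
  } else {
    q <- labeled_data(expr, resp, genes)
    b <- baseline_fit(method, q, train_fraction, seed)
    list(predict = function(e) predict_baseline(b, t(e[genes, , drop = FALSE])),
         model = b)
  }
}

#' Baseline regressors: plain SVR and linear regression
#'
#' Trains the baseline on the same seeded 75/25 split protocol as kESVR and
#' reports the same metrics, so comparisons are apples-to-apples. The SVR
#' baseline is exactly the global-SVR procedure; the linear baseline is
#' ordinary least squares (rank-deficient fits use the pivoted-QR
#' convention, aliased coefficients set to zero).
#'
#' @param kind `"svr"` or `"linear"`.
#' @param q A `kesvr_labeled`.
#' @param train_fraction,seed Split parameters, as in [train_global_svr()].
#' @return Object of class `kesvr_baseline`: list with `kind`, `model`,
#'   `split` and `report` (train/test/avg MSE and R squared on all cells).
#' @export
baseline_fit <- function(kind = c("svr", "linear"), q, train_fraction = 0.75,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(q, "kesvr_labeled"))
  if (kind == "svr") {
    g <- train_global_svr(q, train_fraction, seed)
    model <- g$model; split <- g$split
  } else {
    n <- nrow(q$features)
    idx <- split_indices(n, train_fraction, seed)
    cells <- rownames(q$features)
    split <- list(train = cells[idx$train], test = cells[idx$test],
                  seed = seed, fraction = train_fraction)
    X <- cbind(1, q$features[split$train, , drop = FALSE])
    fit <- stats::lm.fit(X, q$labels[split$train])
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    model <- list(coefs = coefs)
  }
  b <- structure(list(kind = kind, model = model, split = split),
                 class = "kesvr_baseline")
  pred_all <- predict_baseline(b, q$features)
  m_train <- mse(q$labels[split$train], pred_all[split$train])
  m_test <- mse(q$labels[split$test], pred_all[split$test])
  b$report <- list(train_mse = m_train, test_mse = m_test,
                   avg_mse = avg_mse(m_train, m_test),
                   r_squared = r_squared(q$labels, pred_all))
  b
}

#' Predict from a fitted baseline
#'
#' @param b A `kesvr_baseline`.
#' @param features Cells x genes feature matrix.
#' @return Named numeric predictions.
#' @export
predict_baseline <- function(b, features) {
  stopifnot(inherits(b, "kesvr_baseline"))
  if (b$kind == "svr") return(predict(b$model, features))
  drop(cbind(1, as.matrix(features)) %*% b$model$coefs)
}
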