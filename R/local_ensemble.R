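#' Train one local SVR per cluster
#'
#' Each cluster gets its own seeded 75/25 split and an RBF SVR under the same
#' hyperparameter policy as the global model ([fit_svr()]). Clusters with
#' fewer than 4 members are fitted on all members with no split; clusters
#' with fewer than 2 members get a constant predictor at the member mean.
#' Cluster j consumes seed `seed + j - 1`, so a single-cluster partition
#' reproduces the global-SVR training procedure exactly.
#'
#' @param q A `kesvr_labeled` over all cells.
#' @param part A `kesvr_partition` of the same cells.
#' @param train_fraction Fraction for the per-cluster splits.
#' @param seed Integer base seed.
#' @return Object of class `kesvr_localset`: list with `k` and `clusters`, a
#'   list holding per cluster the fitted `model`, `members`, `train` and
#'   `test` cell ids.
#' @export
train_local_svrs <- function(q, part, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(q, "kesvr_labeled"), inherits(part, "kesvr_partition"))
  cells <- rownames(q$features)
  stopifnot(setequal(cells, names(part$labels)))
  clusters <- vector("list", part$k)
  for (j in seq_len(part$k)) {
    members <- cells[part$labels[cells] == j]
    nj <- length(members)
    if (nj < 1L) stop_kesvr("cluster ", j, " is empty")
    if (nj < 4L) {
      train <- members; test <- character(0)
    } else {
      idx <- split_indices(nj, train_fraction, seed + j - 1L)
      train <- members[idx$train]; test <- members[idx$test]
    }
    model <- fit_svr(q$features[train, , drop = FALSE], q$labels[train])
    if (model$type == "constant" && nj < 2L)
      message("cluster ", j, " has a single member; using a constant predictor")
    clusters[[j]] <- list(model = model, members = members,
                          train = train, test = test)
  }
  structure(list(k = part$k, clusters = clusters), class = "kesvr_localset")
}

#' Candidate predictions from every local SVR
#'
#' @param models A `kesvr_localset`.
#' @param x_features Target-gene feature vector (or 1-row matrix) for one
#'   input, or a cells x genes matrix for several.
#' @return Numeric matrix, inputs x clusters: one candidate AUC per cluster.
#' @export
predict_candidates <- function(models, x_features) {
  stopifnot(inherits(models, "kesvr_localset"))
  if (is.null(dim(x_features)))
    x_features <- matrix(x_features, nrow = 1L,
                         dimnames = list(NULL, names(x_features)))
  out <- vapply(models$clusters,
                function(cl) unname(predict(cl$model, x_features)),
                numeric(nrow(x_features)))
  out <- matrix(out, nrow = nrow(x_features),
                dimnames = list(rownames(x_features),
                                paste0("k", seq_len(models$k))))
  if (!all(is.finite(out))) stop_kesvr("non-finite candidate prediction")
  out
}

#' Radius ladder from the clustered reduced dataset
#'
#' Per cluster, the AUC (abscissa) distance between its two farthest points;
#' the spans sorted ascending form the ladder, and the active radius is the
#' smallest entry. When a prediction instance finds zero neighbours in every
#' cluster, selection escalates to the next higher rung.
#'
#' @param z A clustered `kesvr_reduced` (see [transfer_partition()]).
#' @return Object of class `kesvr_ladder`: list with `spans` (ascending
#'   numeric vector, one per cluster) and `r` (the smallest span).
#' @export
compute_radius_ladder <- function(z) {
  stopifnot(inherits(z, "kesvr_reduced"), !is.null(z$cluster))
  spans <- as.numeric(tapply(z$auc, z$cluster, function(a) max(a) - min(a)))
  spans <- sort(spans)
  structure(list(spans = spans, r = spans[1L]), class = "kesvr_ladder")
}

#' Neighbours of a candidate point within a cluster
#'
#' All points of the cluster whose Euclidean distance in the raw (AUC,
#' principal-component) plane from the candidate point is at most `r`
#' (closed ball).
#'
#' @param cluster_points Data frame with columns `cell`, `auc`, `pc` (one
#'   cluster's subset of the reduced dataset).
#' @param point Numeric length-2 vector: the candidate point (AUC value,
#'   ordinate).
#' @param r Radius (>= 0).
#' @return Character vector of neighbour cell ids.
#' @export
find_neighbors <- function(cluster_points, point, r) {
  stopifnot(r >= 0, length(point) == 2L)
  d2 <- (cluster_points$auc - point[1L])^2 + (cluster_points$pc - point[2L])^2
  cluster_points$cell[d2 <= r^2]
}

#' Neighbourhood-averaged Spearman score
#'
#' Mean Spearman rank correlation between the input's target-gene vector and
#' each neighbour cell line's target-gene vector. An empty neighbour set
#' scores 0; a constant expression profile (rank correlation undefined)
#' contributes 0 to the average. The score always lies in [-1, 1].
#'
#' @param x_features Input target-gene vector.
#' @param neighbor_ids Cell ids of the neighbours.
#' @param training_features Cells x genes matrix of training profiles.
#' @return Scalar score in [-1, 1].
#' @export
beta_score <- function(x_features, neighbor_ids, training_features) {
  if (length(neighbor_ids) == 0L) return(0)
  xn <- rank_normalize(x_features)
  if (is.null(xn)) return(0)
  sp <- vapply(neighbor_ids, function(id) {
    yn <- rank_normalize(training_features[id, ])
    if (is.null(yn)) 0 else sum(xn * yn)
  }, numeric(1))
  mean(sp)
}

# Selection core shared by fitting and prediction. `sp` holds the Spearman
# correlation of the input profile with every training cell (constant
# profiles already zeroed); `zc` is the clustered reduced dataset.
select_prediction_impl <- function(id, candidates, phi, zc, ladder, sp,
                                   global_value) {
  k <- length(candidates)
  rungs <- sort(unique(ladder$spans))
  cluster_idx <- split(seq_len(nrow(zc)), zc$cluster)
  for (r in rungs) {
    counts <- integer(k); betas <- numeric(k)
    neigh <- vector("list", k)
    for (j in seq_len(k)) {
      rows <- cluster_idx[[as.character(j)]]
      d2 <- (zc$auc[rows] - candidates[j])^2 + (zc$pc[rows] - phi)^2
      hit <- rows[d2 <= r^2]
      neigh[[j]] <- hit
      counts[j] <- length(hit)
      betas[j] <- if (length(hit)) mean(sp[hit]) else 0
    }
    if (any(counts > 0L)) {
      best <- which(betas == max(betas))
      if (length(best) > 1L) best <- best[counts[best] == max(counts[best])]
      sel <- best[1L]                                  # lowest cluster index
      return(list(id = id, psi = unname(candidates[sel]), cluster = sel,
                  radius = r, fallback = FALSE,
                  candidates = data.frame(cluster = seq_len(k),
                                          value = unname(candidates),
                                          n_neighbors = counts, beta = betas)))
    }
  }
  # ladder exhausted with all-empty neighbourhoods: global-SVR fallback
  list(id = id, psi = unname(global_value), cluster = NA_integer_,
       radius = rungs[length(rungs)], fallback = TRUE,
       candidates = data.frame(cluster = seq_len(k),
                               value = unname(candidates),
                               n_neighbors = integer(k), beta = numeric(k)))
}

#' Select the ensemble prediction among per-cluster candidates
#'
#' Computes each candidate's neighbourhood in its own cluster at the active
#' radius (the smallest ladder rung), scores candidates by the
#' neighbourhood-averaged Spearman correlation, and returns the candidate
#' with the highest score. If every candidate has an empty neighbourhood the
#' radius escalates to the next rung; if the ladder is exhausted the global
#' SVR prediction is returned, flagged in the trace. Ties are broken by
#' larger neighbour count, then lower cluster index.
#'
#' @param candidates Numeric vector: one candidate AUC per cluster.
#' @param x_features The input's target-gene vector.
#' @param phi The input's principal-component ordinate.
#' @param zc Clustered reduced dataset (training cells).
#' @param ladder A `kesvr_ladder`.
#' @param training_features Cells x genes matrix of training target-gene
#'   profiles (rows named by cell, matching `zc$cell`).
#' @param global_value Global-SVR prediction for the input (fallback).
#' @param id Input identifier recorded in the trace.
#' @return A prediction trace: list with `id`, `psi` (the selected value),
#'   `cluster`, `radius`, `fallback` and a per-candidate data frame
#'   `candidates` (cluster, value, n_neighbors, beta).
#' @export
select_prediction <- function(candidates, x_features, phi, zc, ladder,
                              training_features, global_value, id = "input") {
  stopifnot(inherits(ladder, "kesvr_ladder"), !is.null(zc$cluster))
  xn <- rank_normalize(x_features)
  rn <- rank_normalize_rows(training_features[zc$cell, , drop = FALSE])
  sp <- if (is.null(xn)) numeric(nrow(zc)) else as.numeric(rn %*% xn)
  select_prediction_impl(id, candidates, phi, zc, ladder, sp, global_value)
}
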