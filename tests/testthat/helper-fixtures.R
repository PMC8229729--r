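# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately re-derive every quantity from first principles and
# never call the package's fast paths.

.fixture_env <- new.env()

# The frozen worked fixture (60 cells, 40 genes, 8 targets, 3 regimes).
worked_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- make_worked_fixture()
  .fixture_env$sim
}

# A fitted model on the worked fixture, shared across tests.
worked_model <- function() {
  if (is.null(.fixture_env$model)) {
    sim <- worked_sim()
    .fixture_env$model <- suppressMessages(
      fit_kesvr(sim$expr, sim$resp, sim$genes, k_max = 6, seed = 1))
  }
  .fixture_env$model
}

fixture_path <- function(...) {
  system.file("extdata", "worked_fixture", ..., package = "kesvr",
              mustWork = TRUE)
}

# Small deterministic expression matrix for unit tests.
tiny_expr <- function(n_genes = 5, n_cells = 4, seed = 11) {
  set.seed(seed)
  matrix(round(rnorm(n_genes * n_cells, 6, 2), 6), n_genes, n_cells,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(n_cells))))
}

# --- independent oracles -------------------------------------------------

# Spearman via explicit rank-then-Pearson; constant vectors score 0.
oracle_spearman <- function(x, y) {
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Quadratic-scan closed-ball neighbour search.
oracle_neighbors <- function(points, center, r) {
  hits <- character(0)
  for (i in seq_len(nrow(points))) {
    d <- sqrt((points$auc[i] - center[1])^2 + (points$pc[i] - center[2])^2)
    if (d <= r) hits <- c(hits, points$cell[i])
  }
  hits
}

# Dense eigendecomposition of the sample covariance, with the package's
# sign convention applied independently.
oracle_pca <- function(mat) {
  cv <- stats::cov(t(mat))
  eig <- eigen(cv, symmetric = TRUE)
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(values = eig$values, vectors = vec)
}

# Literal step-by-step replay of the ensemble prediction for one input:
# manual projection, per-cluster candidate, brute-force neighbours at each
# ladder rung, per-pair Spearman averages, argmax with the documented
# tie-break (larger neighbour count, then lower cluster index).
oracle_replay <- function(model, x_expr_col) {
  phi <- sum((x_expr_col[names(model$pca_center)] - model$pca_center) *
               model$pca_loading)
  xf <- x_expr_col[model$genes]
  k <- model$local_models$k
  cand <- vapply(model$local_models$clusters,
                 function(cl) unname(predict(cl$model, xf)), numeric(1))
  zc <- model$z
  rungs <- sort(unique(model$ladder$spans))
  for (r in rungs) {
    counts <- integer(k); betas <- numeric(k)
    for (j in seq_len(k)) {
      pts <- zc[zc$cluster == j, , drop = FALSE]
      nb <- oracle_neighbors(pts, c(cand[j], phi), r)
      counts[j] <- length(nb)
      betas[j] <- if (length(nb) == 0L) 0 else
        mean(vapply(nb, function(id)
          oracle_spearman(xf, model$train_features[id, ]), numeric(1)))
    }
    if (any(counts > 0L)) {
      best <- which(betas == max(betas))
      if (length(best) > 1L) best <- best[counts[best] == max(counts[best])]
      sel <- best[1L]
      return(list(psi = unname(cand[sel]), cluster = sel, radius = r,
                  counts = counts, betas = betas, fallback = FALSE))
    }
  }
  list(psi = unname(predict(model$global_svr, xf)), cluster = NA_integer_,
       radius = rungs[length(rungs)], counts = integer(k),
       betas = numeric(k), fallback = TRUE)
}

# Direct SVR decision-function re-evaluation from the stored libsvm pieces.
oracle_svr_eval <- function(svr, x) {
  stopifnot(svr$type == "svm")
  xs <- (x - svr$center) / svr$scale
  fit <- svr$fit
  kern <- exp(-svr$gamma * colSums((t(fit$SV) - xs)^2))
  sum(fit$coefs * kern) - fit$rho
}
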