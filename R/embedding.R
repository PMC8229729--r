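#' Principal-component embedding of an expression matrix
#'
#' Covariance PCA over cell lines (observations = cells, variables = genes),
#' computed by thin SVD of the centred data so the gene dimension may far
#' exceed the number of cells. No per-gene scaling is applied. Each loading
#' vector's sign is fixed so that its largest-magnitude entry is positive,
#' making the embedding geometry reproducible across runs and platforms.
#'
#' @param expr Numeric matrix, genes x cells, with dimnames.
#' @return Object of class `kesvr_pca` with elements `center` (per-gene
#'   means), `loadings` (genes x components, orthonormal columns),
#'   `var_explained` (per-component variance, non-increasing) and
#'   `total_var` (sum of per-gene variances).
#' @export
fit_pca <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop_kesvr("PCA needs at least 2 cell lines")
  pr <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  var_explained <- pr$sdev^2
  total_var <- sum(var_explained)
  if (total_var <= .Machine$double.eps * nrow(expr))
    stop_kesvr("degenerate expression data: zero variance across cell lines")
  loadings <- pr$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(list(center = pr$center,
                 loadings = loadings,
                 var_explained = var_explained,
                 total_var = total_var),
            class = "kesvr_pca")
}

#' Choose the principal component used for the reduced dataset
#'
#' The first component minimises the variance lost by the 1-D reduction, so
#' the default is `p = 1`; an explicit override is honoured for
#' experimentation.
#'
#' @param embedding A `kesvr_pca`.
#' @param p_override Optional component index.
#' @return Integer component index.
#' @export
select_component <- function(embedding, p_override = NULL) {
  stopifnot(inherits(embedding, "kesvr_pca"))
  m <- ncol(embedding$loadings)
  if (is.null(p_override)) return(1L)
  p <- as.integer(p_override)
  if (length(p) != 1L || is.na(p) || p < 1L || p > m)
    stop_kesvr("component override ", p_override, " outside 1..", m)
  p
}

#' Project cell lines onto one principal component
#'
#' @param embedding A `kesvr_pca`.
#' @param expr Expression matrix containing every gene of the embedding.
#' @param p Component index.
#' @return Named numeric vector of projections, one per cell.
#' @export
project_cells <- function(embedding, expr, p) {
  genes <- names(embedding$center)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop_kesvr("expression matrix lacks ", length(missing),
               " gene(s) of the embedding, e.g. ",
               paste(utils::head(missing, 5L), collapse = ", "))
  centred <- expr[genes, , drop = FALSE] - embedding$center
  drop(crossprod(centred, embedding$loadings[, p]))
}

#' Build the reduced dataset Z
#'
#' One 2-D point per aligned cell line: the drug-response AUC on the abscissa
#' and the projection onto principal component `p` on the ordinate. This is
#' the plane in which clustering geometry, neighbour search and ensemble
#' selection operate.
#'
#' @param embedding A `kesvr_pca`.
#' @param expr Aligned expression matrix.
#' @param resp Aligned `kesvr_response` (no missing values).
#' @param p Component index.
#' @return A data frame of class `kesvr_reduced` with columns `cell`, `auc`,
#'   `pc`; attribute `p` records the component used.
#' @export
build_reduced_dataset <- function(embedding, expr, resp, p) {
  cells <- colnames(expr)
  stopifnot(identical(cells, names(resp$auc)), !anyNA(resp$auc))
  phi <- project_cells(embedding, expr, p)
  z <- data.frame(cell = cells, auc = unname(resp$auc), pc = unname(phi),
                  stringsAsFactors = FALSE)
  structure(z, p = as.integer(p), class = c("kesvr_reduced", "data.frame"))
}
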