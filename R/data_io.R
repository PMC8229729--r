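#' Read a gene-expression matrix
#'
#' Reads a genes x cell-lines expression table. The first row holds the
#' cell-line identifiers, the first column the gene identifiers. The field
#' separator (tab or comma) is detected from the header line. Expression
#' values must be numeric and finite: missing expression is not supported
#' and is rejected with the offending coordinates.
#'
#' @param path Path to a TSV/CSV file.
#' @return A numeric matrix (genes x cells) with gene ids as row names and
#'   cell-line ids as column names, in file order.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_kesvr("expression file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", colClasses = "character")
  if (ncol(df) < 2L) stop_kesvr("expression file needs a gene-id column and >= 1 cell column")
  gene_ids <- df[[1L]]
  cell_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop_kesvr("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop_kesvr("duplicate cell-line ids in header: ", paste(dup_c, collapse = ", "))
  vals <- matrix(NA_real_, length(gene_ids), length(cell_ids),
                 dimnames = list(gene_ids, cell_ids))
  for (j in seq_along(cell_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_kesvr("non-numeric or missing expression value at gene '",
                 gene_ids[bad[1L]], "', cell '", cell_ids[j], "'")
    vals[, j] <- v
  }
  vals
}

#' Write a gene-expression matrix
#'
#' Writes the canonical tab-separated dialect read by
#' [read_expression_matrix()]. Values are printed with \code{\%.17g} so that
#' read/write round-trips preserve doubles exactly.
#'
#' @param mat Numeric matrix, genes x cells, with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Construct a drug-response vector
#'
#' @param drug Drug identifier.
#' @param auc Named numeric vector of AUC values (names = cell-line ids);
#'   `NA` marks a missing response.
#' @return An object of class `kesvr_response`.
#' @export
response_vector <- function(drug, auc) {
  if (is.null(names(auc)) || anyNA(names(auc)))
    stop_kesvr("auc must be named by cell-line id")
  dup <- unique(names(auc)[duplicated(names(auc))])
  if (length(dup)) stop_kesvr("duplicate cell-line ids: ", paste(dup, collapse = ", "))
  if (any(is.infinite(auc))) stop_kesvr("non-finite AUC values present")
  structure(list(drug = drug, auc = auc), class = "kesvr_response")
}

#' Read one drug's response row from a response table
#'
#' The table holds drugs as rows and cell lines as columns by default
#' (`orientation = "drugs"`); pass `orientation = "cells"` for the transposed
#' layout. Empty fields, `NA` and `NaN` are flagged as missing responses, not
#' dropped.
#'
#' @param path Path to a TSV/CSV response table of AUC values.
#' @param drug Drug identifier to extract.
#' @param orientation `"drugs"` (drugs as rows, default) or `"cells"`.
#' @return A `kesvr_response` (see [response_vector()]); missing entries are
#'   `NA` in `$auc`.
#' @export
read_response_table <- function(path, drug, orientation = c("drugs", "cells")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_kesvr("response file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", colClasses = "character",
                          na.strings = c("NA", "NaN", ""))
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  if (orientation == "cells") { # columns are drugs
    drugs <- col_ids; cells <- row_ids
  } else {
    drugs <- row_ids; cells <- col_ids
  }
  if (!drug %in% drugs) {
    near <- agrep(drug, drugs, max.distance = 0.25, value = TRUE)
    hint <- if (length(near)) paste0("; did you mean: ", paste(near, collapse = ", "), "?") else ""
    stop_kesvr("drug '", drug, "' not found in ", path, hint)
  }
  raw <- if (orientation == "cells") df[[which(col_ids == drug) + 1L]]
         else unlist(df[which(row_ids == drug)[1L], -1L], use.names = FALSE)
  auc <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(auc))
  if (length(bad))
    stop_kesvr("non-numeric AUC for drug '", drug, "', cell '", cells[bad[1L]], "'")
  names(auc) <- cells
  response_vector(drug, auc)
}

#' Read a target-gene list
#'
#' One identifier per line; `#` starts a comment; blank lines are skipped;
#' duplicates are removed (first occurrence kept).
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_kesvr("gene list not found: ", path)
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Align expression, response and target genes
#'
#' Restricts both inputs to the cell lines present in each with a recorded
#' (non-missing) AUC, sorted lexicographically so that every seeded split
#' downstream is reproducible regardless of file ordering. The target-gene
#' subset is intersected with the matrix genes (absent subset = all genes).
#'
#' @param expr Expression matrix from [read_expression_matrix()].
#' @param resp A `kesvr_response`.
#' @param genes Optional character vector of target genes.
#' @return List with elements `expr` (all genes, aligned cells), `resp`
#'   (aligned, no missing values) and `genes` (the effective target subset).
#' @export
align_inputs <- function(expr, resp, genes = NULL) {
  stopifnot(is.matrix(expr), inherits(resp, "kesvr_response"))
  present <- names(resp$auc)[!is.na(resp$auc)]
  cells <- sort_ids(intersect(colnames(expr), present))
  if (length(cells) < 10L)
    stop_kesvr("only ", length(cells), " cell lines shared between expression and ",
               "response for drug '", resp$drug, "'; need >= 10 to split and cluster")
  if (is.null(genes)) {
    genes <- rownames(expr)
  } else {
    missing <- setdiff(genes, rownames(expr))
    genes <- genes[genes %in% rownames(expr)]
    if (length(missing))
      warning(length(missing), " target gene(s) absent from the expression matrix were dropped",
              call. = FALSE)
    if (!length(genes)) stop_kesvr("no target genes left after intersecting with the matrix")
    genes <- unique(genes)
  }
  list(expr = expr[, cells, drop = FALSE],
       resp = response_vector(resp$drug, resp$auc[cells]),
       genes = genes)
}

ARCHIVE_FORMAT <- "kesvr-archive"
ARCHIVE_VERSION <- 1L

#' Save / load a fitted kESVR model
#'
#' The archive is a versioned single-file container whose round trip
#' reproduces every prediction bit-identically.
#'
#' @param model A fitted `kesvr_model` from [fit_kesvr()].
#' @param path Destination file.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   `kesvr_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "kesvr_model")) stop_kesvr("not a fitted kesvr_model")
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop_kesvr("cannot write model archive to '", path, "'")
  archive <- list(
    format = ARCHIVE_FORMAT,
    version = ARCHIVE_VERSION,
    fingerprint = list(drug = model$drug,
                       n_cells = length(model$cells),
                       n_target_genes = length(model$genes),
                       seed = model$seed),
    model = model)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_kesvr("model archive not found: ", path)
  archive <- tryCatch(readRDS(path), error = function(e)
    stop_kesvr("corrupt or truncated model archive: ", path))
  if (!is.list(archive) || !identical(archive$format, ARCHIVE_FORMAT))
    stop_kesvr("not a kesvr model archive: ", path)
  if (!identical(archive$version, ARCHIVE_VERSION))
    stop_kesvr("model archive version ", archive$version,
               " not supported (expected ", ARCHIVE_VERSION, ")")
  archive$model
}
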