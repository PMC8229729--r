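#' Specification for the synthetic expression/response generator
#'
#' The generator emulates the data shape the method targets: a
#' high-dimensional expression matrix in which a small target-gene subset
#' drives drug response through several distinct nonlinear regimes, plus
#' additive Gaussian noise and optional missing responses. Defaults are the
#' package's reference study conditions: 300 cells, 1000 genes, 50 target
#' genes, 3 regimes, noise sd 0.3 AUC units, regime mean offsets of 4 times
#' the within-regime expression sd, regime response levels spaced 4 AUC
#' units apart.
#'
#' @param n_cells,n_genes,n_target_genes,n_regimes Dimensions of the
#'   dataset.
#' @param noise_sd Additive response noise sd, AUC units.
#' @param missing_frac Fraction of responses masked as missing.
#' @param separation Between-regime target-gene mean offset, in units of the
#'   within-regime expression sd (1).
#' @param seed Integer seed; all output is fully seeded.
#' @return Object of class `kesvr_synth_spec`.
#' @export
synthetic_spec <- function(n_cells = 300L, n_genes = 1000L,
                           n_target_genes = 50L, n_regimes = 3L,
                           noise_sd = 0.3, missing_frac = 0,
                           separation = 4, seed = 1L) {
  if (n_target_genes > n_genes)
    stop_kesvr("n_target_genes exceeds n_genes")
  if (n_regimes < 1L) stop_kesvr("n_regimes must be >= 1")
  if (noise_sd < 0) stop_kesvr("noise_sd must be >= 0")
  if (missing_frac < 0 || missing_frac >= 1)
    stop_kesvr("missing_frac must lie in [0, 1)")
  if (n_cells < n_regimes) stop_kesvr("need at least one cell per regime")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_target_genes = as.integer(n_target_genes),
                 n_regimes = as.integer(n_regimes), noise_sd = noise_sd,
                 missing_frac = missing_frac, separation = separation,
                 seed = as.integer(seed)),
            class = "kesvr_synth_spec")
}

# Regime response functions of the regime-standardised latent score u
# (~ N(0,1) within each regime). Levels are spaced `level_step` apart so the
# regimes occupy distinct AUC bands; the functional forms cycle
# linear / quadratic / sinusoid so that a single global regression is
# genuinely mis-specified and a local ensemble has something to win.
regime_response <- function(regime, u, level_step = 4) {
  base <- 8 + (regime - 1L) * level_step
  form <- (regime - 1L) %% 3L + 1L
  out <- numeric(length(u))
  i <- form == 1L; out[i] <- base[i] + 1.5 * u[i]              # linear
  i <- form == 2L; out[i] <- base[i] + 1.0 * (u[i]^2 - 1)      # quadratic
  i <- form == 3L; out[i] <- base[i] + 1.5 * sin(2 * u[i])     # sinusoid
  out
}

#' Generate a synthetic expression/response dataset with planted regimes
#'
#' Cells are assigned to regimes in balanced proportions. Every gene has a
#' shared per-gene baseline mean (so any two cells' profiles are strongly
#' positively rank-correlated, as in real expression data). Target genes
#' form a one-factor co-expression module with regime-specific mean offsets
#' of `separation/2` within-regime sds per gene (differing regimes are
#' `separation` sds apart on differing genes); non-target genes are pure
#' noise around their baselines. The response is a regime-specific function
#' (linear, quadratic or sinusoid) of a regime-standardised latent score —
#' the fixed positive loading-weighted sum of the target genes — plus
#' Gaussian noise; a requested fraction of responses is masked.
#'
#' @param spec A `kesvr_synth_spec`.
#' @return List with `expr` (matrix), `resp` (`kesvr_response`), `genes`
#'   (target ids) and `truth` (`kesvr_truth` data frame: cell, regime,
#'   response_true; attributes `weights`, `offsets`, `spec`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "kesvr_synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells; G <- spec$n_genes
    nt <- spec$n_target_genes; R <- spec$n_regimes
    cells <- sprintf("cl%04d", seq_len(n))
    genes <- sprintf("g%05d", seq_len(G))
    target <- genes[seq_len(nt)]
    regime <- sample(rep_len(seq_len(R), n))

    # Per-gene baseline means shared by every cell: real expression profiles
    # of any two cell lines are strongly positively rank-correlated because
    # gene-level baseline expression dominates. The baseline is invisible to
    # the (per-gene centred) PCA and the (standardised) SVR features but
    # carries that property to the Spearman-based selection score.
    base <- stats::rnorm(G, mean = 6, sd = 3)
    # The target panel carries two co-expression programs with disjoint gene
    # support: a response-driving activity f loading on the first half of
    # the panel, and a response-unrelated nuisance program h (think lineage
    # or a co-regulated but irrelevant pathway) on the second half. Cells
    # with similar activity therefore have measurably more similar profiles
    # (graded similarity, as in real co-regulated pathways), but profile
    # similarity is also confounded by the nuisance program, so
    # similarity-based selection is informative without being clairvoyant.
    n_sig <- ceiling(nt / 2)
    lam <- c(stats::runif(n_sig, 0.3, 1.3), rep(0, nt - n_sig))
    mu <- c(rep(0, n_sig), stats::runif(nt - n_sig, 0.3, 1.3))
    eps_sd <- 0.6
    sd_within <- sqrt(lam^2 + mu^2 + eps_sd^2)   # per-gene within-regime sd
    offsets <- matrix(sample(c(-1, 1), R * nt, replace = TRUE), R, nt) *
      (spec$separation / 2) * rep(sd_within, each = R)
    f <- stats::rnorm(n)
    h <- stats::rnorm(n)
    expr <- base + matrix(stats::rnorm(G * n, mean = 0, sd = 1), G, n,
                          dimnames = list(genes, cells))
    expr[seq_len(nt), ] <- base[seq_len(nt)] + t(offsets[regime, , drop = FALSE]) +
      lam %o% f + mu %o% h +
      matrix(stats::rnorm(nt * n, 0, eps_sd), nt, n)

    # Latent score: the loading-weighted sum of the target genes, regime-
    # centred and scaled to unit variance. The weights are fixed,
    # non-negative, supported on the response program, and published with
    # the truth; the score is an exact linear function of the realised
    # target-gene values.
    centred <- expr[seq_len(nt), , drop = FALSE] - base[seq_len(nt)] -
      t(offsets[regime, , drop = FALSE])
    norm_const <- sqrt(sum(lam^2)^2 + sum(lam^2) * eps_sd^2)
    u <- drop(crossprod(centred, lam)) / norm_const
    response_true <- regime_response(regime, u)
    auc <- response_true + stats::rnorm(n, sd = spec$noise_sd)
    if (spec$missing_frac > 0) {
      n_miss <- round(spec$missing_frac * n)
      auc[sample.int(n, n_miss)] <- NA_real_
    }
    truth <- structure(data.frame(cell = cells, regime = regime,
                                  response_true = response_true,
                                  stringsAsFactors = FALSE),
                       weights = lam, norm_const = norm_const,
                       offsets = offsets, baseline = base, spec = spec,
                       class = c("kesvr_truth", "data.frame"))
    list(expr = expr,
         resp = response_vector("synthetic_drug", stats::setNames(auc, cells)),
         genes = target,
         truth = truth)
  })
}

#' Write a synthetic dataset to the standard on-disk formats
#'
#' Produces the expression TSV, response TSV (drugs as rows), target-gene
#' list and a truth TSV readable back by the data-io module.
#'
#' @param sim Output of [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             response = file.path(dir, "response.tsv"),
             genes = file.path(dir, "genes.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(sim$expr, paths[["expression"]])
  con <- file(paths[["response"]], "w")
  writeLines(paste(c("drug_id", names(sim$resp$auc)), collapse = "\t"), con)
  writeLines(paste(c(sim$resp$drug,
                     ifelse(is.na(sim$resp$auc), "NA",
                            sprintf("%.17g", sim$resp$auc))),
                   collapse = "\t"), con)
  close(con)
  writeLines(c("# synthetic target genes", sim$genes), paths[["genes"]])
  utils::write.table(format(sim$truth, digits = 17),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' The frozen worked fixture
#'
#' A deterministic 60-cell, 40-gene, 8-target-gene, 3-regime dataset (seed
#' 844) used throughout the test suite and shipped as plain TSV under
#' `inst/extdata/worked_fixture/`. Regenerating it always yields identical
#' content.
#'
#' @return As [generate_synthetic()].
#' @export
make_worked_fixture <- function() {
  generate_synthetic(synthetic_spec(n_cells = 60L, n_genes = 40L,
                                    n_target_genes = 8L, n_regimes = 3L,
                                    noise_sd = 0.3, missing_frac = 0,
                                    separation = 4, seed = 844L))
}
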