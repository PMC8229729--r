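# Shared pipeline state on the worked fixture, built once per file.
pipe <- local({
  sim <- make_worked_fixture()
  al <- align_inputs(sim$expr, sim$resp, sim$genes)
  q <- labeled_data(al$expr, al$resp, al$genes)
  g <- train_global_svr(q, seed = 844)
  res <- compute_residuals(g$model, q)
  part <- cluster_residuals(res, 3, seed = 844)
  emb <- fit_pca(al$expr)
  z <- build_reduced_dataset(emb, al$expr, al$resp, 1)
  zc <- transfer_partition(z, part)
  locals <- suppressMessages(train_local_svrs(q, part, seed = 844))
  list(sim = sim, al = al, q = q, g = g, res = res, part = part, zc = zc,
       locals = locals, ladder = compute_radius_ladder(zc))
})

test_that("per-cluster training follows the split and small-cluster rules", {
  locals <- pipe$locals
  expect_equal(locals$k, 3L)
  for (j in 1:3) {
    cl <- locals$clusters[[j]]
    expect_setequal(c(cl$train, cl$test), cl$members)
    if (length(cl$members) >= 4)
      expect_equal(length(cl$train), round(0.75 * length(cl$members)))
    else
      expect_length(cl$test, 0)
  }
  # a 3-member cluster is fitted on all members; a singleton gets a
  # constant model at its member mean
  qs <- pipe$q
  lab3 <- setNames(c(rep(1L, nrow(qs$features) - 1L), 2L),
                   rownames(qs$features))
  part3 <- structure(list(k = 2L, labels = lab3,
                          centroids = matrix(0, 2, 2), sizes = c(59L, 1L),
                          tot_withinss = 0),
                     class = "kesvr_partition")
  ls3 <- suppressMessages(train_local_svrs(qs, part3, seed = 1))
  singleton <- ls3$clusters[[2]]
  expect_equal(singleton$model$type, "constant")
  expect_equal(singleton$model$value,
               unname(qs$labels[singleton$members]))
})

test_that("single-cluster training reproduces the global-SVR procedure", {
  q <- pipe$q
  part1 <- cluster_residuals(pipe$res, 1, seed = 844)
  ls1 <- train_local_svrs(q, part1, seed = 844)
  g <- train_global_svr(q, seed = 844)
  expect_identical(sort(ls1$clusters[[1]]$train), sort(g$split$train))
  expect_identical(predict(ls1$clusters[[1]]$model, q$features),
                   predict(g$model, q$features))
  cand <- predict_candidates(ls1, q$features)
  expect_identical(unname(cand[, 1]), unname(predict(g$model, q$features)))
})

test_that("candidates match independent per-model re-evaluation", {
  cand <- predict_candidates(pipe$locals, pipe$q$features[1:5, ])
  expect_equal(dim(cand), c(5L, 3L))
  for (i in 1:5) for (j in 1:3)
    expect_equal(cand[i, j],
                 unname(predict(pipe$locals$clusters[[j]]$model,
                                pipe$q$features[i, ])),
                 tolerance = 1e-14)
  expect_error(predict_candidates(pipe$locals, pipe$q$features[, 1:3]),
               "mismatch")
})

test_that("radius ladder holds sorted per-cluster AUC spans", {
  zc <- pipe$zc
  lad <- pipe$ladder
  spans <- sort(as.numeric(tapply(zc$auc, zc$cluster, function(a) diff(range(a)))))
  expect_equal(lad$spans, spans)
  expect_equal(lad$r, min(spans))
  # hand-built cases
  z1 <- structure(data.frame(cell = c("a", "b", "c"), auc = c(0, 1, 5),
                             pc = 0, cluster = 1L),
                  p = 1L, class = c("kesvr_reduced", "data.frame"))
  expect_equal(compute_radius_ladder(z1)$spans, 5)
  z2 <- z1; z2$cluster <- c(1L, 1L, 2L); z2$auc <- c(0, 7, 3)
  l2 <- compute_radius_ladder(z2)
  expect_equal(l2$spans, c(0, 7))
  expect_equal(l2$r, 0)
})

test_that("neighbour search equals the brute-force quadratic scan", {
  # hand-placed points around the origin, r = 2.5
  pts <- data.frame(cell = paste0("p", 1:5),
                    auc = c(0, 2, 3, -1, 0), pc = c(1, 1, 0, -2, 2.5),
                    stringsAsFactors = FALSE)
  expect_setequal(find_neighbors(pts, c(0, 0), 2.5),
                  oracle_neighbors(pts, c(0, 0), 2.5))
  expect_setequal(find_neighbors(pts, c(0, 0), 2.5), c("p1", "p2", "p4", "p5"))
  # closed ball: boundary point included; r = 0 without coincidence is empty
  expect_true("p5" %in% find_neighbors(pts, c(0, 0), 2.5))
  expect_length(find_neighbors(pts, c(10, 10), 0), 0)
  expect_setequal(find_neighbors(pts, c(0.5, 0.5), 100), pts$cell)
  # randomised agreement with the oracle
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    rp <- data.frame(cell = paste0("q", 1:n), auc = runif(n, 0, 10),
                     pc = rnorm(n, 0, 3), stringsAsFactors = FALSE)
    ctr <- c(runif(1, 0, 10), rnorm(1, 0, 3))
    r <- runif(1, 0, 5)
    expect_setequal(find_neighbors(rp, ctr, r), oracle_neighbors(rp, ctr, r))
  }
})

test_that("beta score is a neighbour-averaged Spearman with the stated conventions", {
  feats <- pipe$q$features
  x <- feats[1, ]
  ids <- rownames(feats)[2:4]
  expect_equal(beta_score(x, ids, feats),
               mean(vapply(ids, function(id) oracle_spearman(x, feats[id, ]),
                           numeric(1))),
               tolerance = 1e-12)
  # empty neighbourhood scores 0
  expect_identical(beta_score(x, character(0), feats), 0)
  # strictly increasing transforms preserve ranks: all Spearman = 1
  tf <- rbind(a = 2 * x + 1, b = exp(x / 10))
  expect_equal(beta_score(x, c("a", "b"), tf), 1, tolerance = 1e-12)
  # constant profiles contribute 0
  cf <- rbind(flat = rep(1, length(x)), same = x)
  expect_equal(beta_score(x, c("flat", "same"), cf), 0.5, tolerance = 1e-12)
  expect_identical(beta_score(rep(2, length(x)), ids, feats), 0)
  # bounded
  expect_lte(abs(beta_score(x, rownames(feats), feats)), 1)
})

test_that("beta moves toward a duplicated neighbour's correlation", {
  feats <- pipe$q$features
  x <- feats[1, ]
  ids <- rownames(feats)[2:4]
  sp <- vapply(ids, function(id) oracle_spearman(x, feats[id, ]), numeric(1))
  target <- ids[which.max(sp)]
  b0 <- beta_score(x, ids, feats)
  b1 <- beta_score(x, c(ids, target), feats)
  expect_gt(b1, b0)
  expect_lt(abs(b1 - mean(c(sp, max(sp)))), 1e-12)
})

test_that("selection follows max-beta with documented tie-breaks and escalation", {
  # two clusters on the AUC axis; candidates and geometry hand-placed
  zc <- structure(data.frame(cell = paste0("t", 1:6),
                             auc = c(1, 1.4, 2, 11, 11.5, 12),
                             pc = rep(0, 6),
                             cluster = rep(1:2, each = 3)),
                  p = 1L, class = c("kesvr_reduced", "data.frame"))
  set.seed(7)
  core <- rnorm(8, 0, 2)
  tf <- rbind(matrix(rnorm(3 * 8), 3, 8),                  # cluster 1: unrelated
              core + matrix(rnorm(3 * 8, 0, 0.2), 3, 8))   # cluster 2: coherent
  dimnames(tf) <- list(zc$cell, paste0("g", 1:8))
  lad <- compute_radius_ladder(zc)          # spans: 1 and 1
  x <- core + rnorm(8, 0, 0.2)              # input resembling cluster 2
  sel <- select_prediction(c(1.5, 11.4), x, 0, zc, lad, tf,
                           global_value = 99, id = "probe")
  expect_equal(sel$cluster, 2L)
  expect_equal(sel$psi, 11.4)
  expect_false(sel$fallback)
  expect_true(sel$psi %in% sel$candidates$value)
  expect_true(all(abs(sel$candidates$beta) <= 1))

  # candidates far from every cluster point: ladder exhausted -> flagged
  # global fallback
  sel2 <- select_prediction(c(500, 600), x, 400, zc, lad, tf,
                            global_value = 42, id = "faraway")
  expect_true(sel2$fallback)
  expect_equal(sel2$psi, 42)

  # escalation: rung 1 empty everywhere, rung 2 populated
  zc2 <- zc; zc2$cluster <- c(1L, 1L, 1L, 2L, 2L, 2L)
  zc2$auc <- c(0, 0.1, 0.2, 10, 12, 14)     # spans 0.2 and 4
  lad2 <- compute_radius_ladder(zc2)
  x2 <- tf["t1", ]
  sel3 <- select_prediction(c(5, 7.5), x2, 0, zc2, lad2, tf,
                            global_value = 0, id = "ladder")
  expect_equal(sel3$radius, 4)              # escalated past 0.2
  expect_false(sel3$fallback)
})

test_that("neighbourhoods are monotone in the radius", {
  zc <- pipe$zc
  feats <- pipe$q$features
  x <- feats[10, ]
  cand <- predict_candidates(pipe$locals, x)[1, ]
  for (j in 1:3) {
    pts <- zc[zc$cluster == j, ]
    prev <- -1L
    for (r in c(0, 0.5, 2, 5, 20, 1000)) {
      cur <- length(find_neighbors(pts, c(cand[j], zc$pc[10]), r))
      expect_gte(cur, prev)
      prev <- cur
    }
    expect_equal(length(find_neighbors(pts, c(cand[j], zc$pc[10]), 1e6)),
                 nrow(pts))
  }
})
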