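test_that("PCA separates well-separated origins along PC1", {
  ds <- make_separable_dataset(seed = 3)
  p <- suppressWarnings(pca_scores(ds))
  expect_equal(p$dropped, "GCG")
  two <- ds$labels %in% c("FR", "GMEX")
  s1 <- p$scores[two, 1]
  g <- droplevels(ds$labels[two])
  smd <- abs(diff(tapply(s1, g, mean))) /
    sqrt(mean(tapply(s1, g, var)))
  expect_gt(smd, 2)
})

test_that("PCA handles degenerate input and orders variance", {
  feats <- matrix(5, 6, 4, dimnames = list(NULL, c("GC", "EGC", "EC", "CAF")))
  ds <- structure(list(features = feats,
                       labels = factor(rep(c("FR", "GMEX", "YTS"), 2)),
                       sample_ids = letters[1:6]), class = "origin_dataset")
  p <- suppressWarnings(pca_scores(ds, n_components = 2))
  expect_true(all(p$scores == 0))
  expect_equal(p$explained_variance, c(0, 0))

  ds2 <- simulate_origin_dataset(seed = 12)
  p2 <- suppressWarnings(pca_scores(ds2))
  expect_true(all(diff(p2$explained_variance) <= 1e-12))
  expect_equal(sum(p2$proportion), 1, tolerance = 1e-10)
  expect_error(suppressWarnings(pca_scores(ds2, n_components = 50)),
               "exceeds")
})

test_that("triad closure yields proportions summing to one", {
  feats <- matrix(c(50, 25, 25, 10, 0, 0, 0, 0), 1, 8,
                  dimnames = list(NULL, c("EGCG", "EGC", "GC", "EC",
                                          "ECG", "CAF", "CG", "GCG")))
  ds <- structure(list(features = feats, labels = factor("FR"),
                       sample_ids = "s1"), class = "origin_dataset")
  tri <- fca_triads(ds, list(c("EGCG", "EGC", "GC")))[[1]]
  expect_equal(unname(tri$proportions[1, ]), c(0.5, 0.25, 0.25))

  ds2 <- simulate_origin_dataset(seed = 31)
  out <- fca_triads(ds2)
  expect_length(out, 3)
  expect_equal(lapply(out, `[[`, "triad"),
               list(c("EGCG", "EGC", "GC"), c("EC", "EGCG", "EGC"),
                    c("CAF", "ECG", "EC")))
  for (t in out) {
    ok <- !t$flagged
    expect_equal(unname(rowSums(t$proportions[ok, , drop = FALSE])),
                 rep(1, sum(ok)), tolerance = 1e-12)
  }
  # all-zero triad is flagged, not fabricated
  zt <- fca_triads(ds, list(c("ECG", "CAF", "CG")))[[1]]
  expect_true(zt$flagged[1])
  expect_true(all(is.na(zt$proportions[1, ])))
  expect_error(fca_triads(ds, list(c("EGCG", "EGC", "XYZ"))), "unknown")
})

test_that("stratified splits reproduce the 2/2/3 validation composition", {
  ds <- simulate_origin_dataset(seed = 44)
  sp <- split_train_validation(ds, 7, seed = 5)
  expect_equal(as.integer(table(sp$validation$labels)), c(2, 2, 3))
  expect_equal(nrow(sp$train$features), 56)
  expect_setequal(c(sp$train$sample_ids, sp$validation$sample_ids),
                  ds$sample_ids)
  # determinism
  sp2 <- split_train_validation(ds, 7, seed = 5)
  expect_identical(sp$validation_idx, sp2$validation_idx)
  # edge and error cases
  sp0 <- split_train_validation(ds, 0, seed = 1)
  expect_equal(nrow(sp0$validation$features), 0)
  expect_equal(nrow(sp0$train$features), 63)
  expect_error(split_train_validation(ds, 7, strata = c(FR = 23, GMEX = 2,
                                                        YTS = 3)),
               "too small")
})

test_that("LDA achieves perfect accuracy on separable classes", {
  ds <- make_separable_dataset(seed = 7)
  sp <- split_train_validation(ds, 7, seed = 7)
  r <- lda_classify(sp$train, sp$validation)
  expect_equal(r$accuracy, 1)
  expect_equal(dim(r$confusion), c(3L, 3L))
  expect_equal(sum(r$confusion), 7)
})

test_that("label shuffling drives LDA to chance accuracy", {
  accs <- vapply(1:8, function(s) {
    ds <- shuffle_labels(simulate_origin_dataset(seed = s), seed = 100 + s)
    sp <- split_train_validation(ds, 7, seed = s)
    lda_classify(sp$train, sp$validation)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("PLS-DA selects components by CV and reports normalized VIPs", {
  ds <- make_separable_dataset(seed = 9)
  sp <- split_train_validation(ds, 7, seed = 9)
  r <- plsda_classify(sp$train, sp$validation, seed = 9)
  expect_equal(r$accuracy, 1)
  expect_gte(r$n_lv, 1)
  expect_equal(mean(r$vip^2), 1, tolerance = 1e-10)
})

test_that("a single informative feature earns the top VIP score", {
  set.seed(77)
  n <- 60
  feats <- matrix(rnorm(n * 5, 50, 5), n, 5,
                  dimnames = list(NULL, c("GC", "EGC", "EC", "ECG", "CAF")))
  labs <- factor(rep(c("FR", "GMEX", "YTS"), each = n / 3))
  feats <- cbind(feats,
                 EGCG = 50 + 20 * (as.integer(labs) - 2) + rnorm(n, 0, 3))
  ds <- structure(list(features = feats, labels = labs,
                       sample_ids = sprintf("s%02d", 1:n)),
                  class = "origin_dataset")
  sp <- split_train_validation(ds, 9, seed = 2)
  r <- plsda_classify(sp$train, sp$validation, seed = 2)
  expect_equal(names(which.max(r$vip)), "EGCG")
  expect_gt(r$vip["EGCG"], 1)
})

test_that("the L9 array is orthogonal and contains the winning configuration", {
  d <- l9_design()
  expect_equal(nrow(d$runs), 9)
  idx <- d$level_index
  for (f in 1:4)
    expect_equal(as.integer(table(idx[, f])), rep(3L, 3))
  for (f1 in 1:3) for (f2 in (f1 + 1):4) {
    pairs <- table(idx[, f1], idx[, f2])
    expect_true(all(pairs == 1))
  }
  expect_equal(sum(d$runs$perplexity == 50), 3)
  hit <- d$runs$perplexity == 50 & d$runs$learning_rate == 100 &
    d$runs$iterations == 250 & d$runs$early_exaggeration == 12
  expect_equal(sum(hit), 1)
})

test_that("t-SNE embedding is seeded-deterministic and validates input", {
  ds <- simulate_origin_dataset(seed = 3)
  X <- suppressWarnings(scale(ds$features[, colnames(ds$features) != "GCG"]))
  e1 <- tsne_embed(X, dims = 2, perplexity = 20, iterations = 100, seed = 4)
  e2 <- tsne_embed(X, dims = 2, perplexity = 20, iterations = 100, seed = 4)
  expect_identical(e1, e2)
  e3 <- tsne_embed(X, dims = 2, perplexity = 20, iterations = 100, seed = 5)
  expect_false(identical(e1, e3))
  expect_error(tsne_embed(X, perplexity = 100), "perplexity")
  Xd <- X; Xd[1, ] <- 3
  expect_error(tsne_embed(Xd, perplexity = 10), "degenerate")
})

test_that("t-SNE-RF separates well-separated origins and is reproducible", {
  ds <- make_separable_dataset(seed = 11)
  sp <- split_train_validation(ds, 7, seed = 11)
  hyper <- list(perplexity = 15, learning_rate = 100, iterations = 500,
                early_exaggeration = 12)   # neighborhood ~ class size
  r1 <- tsne_rf_classify(ds, sp, hyper = hyper, seed = 11)
  expect_gte(r1$accuracy, 0.85)
  expect_gt(r1$silhouette, 0.5)
  expect_true(r1$silhouette <= 1 && r1$silhouette >= -1)
  expect_equal(dim(r1$embedding_2d), c(63L, 2L))
  expect_equal(dim(r1$embedding_3d), c(63L, 3L))
  r2 <- tsne_rf_classify(ds, sp, hyper = hyper, seed = 11)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("the L9 screen scores all runs and returns the argmax", {
  ds <- make_separable_dataset(seed = 13)
  sp <- split_train_validation(ds, 7, seed = 13)
  opt <- optimize_tsne_rf(ds, sp, seed = 13)
  expect_equal(nrow(opt$scores), 9)
  expect_true(all(is.finite(opt$scores$validation_accuracy)))
  expect_gte(opt$scores$validation_accuracy[opt$best_run],
             median(opt$scores$validation_accuracy))
  # trivially separable data: ties broken to the first best run
  expect_equal(opt$best_run,
               which.max(opt$scores$validation_accuracy))
})
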