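# Column-wise autoscaling (mean 0, SD 1) with zero-variance columns dropped.
# Returns the scaled matrix plus the statistics so validation data can be
# scaled with training-set parameters.
autoscale <- function(X, center = NULL, scale = NULL, warn = TRUE) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  keep <- scale > 0
  if (warn && any(!keep))
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], "/")
  list(X = Xs, center = center, scale = scale, kept = keep)
}

make_confusion <- function(actual, predicted, levels) {
  table(factor(actual, levels = levels), factor(predicted, levels = levels),
        dnn = c("actual", "predicted"))
}

classification_result <- function(method, confusion, silhouette = NA_real_,
                                  ...) {
  total <- sum(confusion)
  structure(list(method = method, confusion = confusion,
                 accuracy = if (total > 0) sum(diag(confusion)) / total
                            else NA_real_,
                 silhouette = silhouette, ...),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: accuracy %.3f%s\n", x$method,
              x$accuracy,
              if (is.finite(x$silhouette))
                sprintf(", silhouette %.2f", x$silhouette) else ""))
  print(x$confusion)
  invisible(x)
}

#' Principal component analysis of an origin dataset
#'
#' Autoscales the analyte table (zero-variance columns such as the always-
#' below-detection GCG are dropped with a warning) and performs PCA on the
#' standardized data, i.e. an eigen-decomposition of the correlation
#' structure. If every column is constant the scores are all zero with zero
#' explained variance.
#'
#' @param dataset An `origin_dataset`.
#' @param n_components Number of components to return (default
#'   `min(n - 1, p)`).
#' @return List: `scores` (sample x component), `explained_variance`
#'   (variances of the scores, non-increasing), `proportion` (fraction of
#'   total retained variance), `loadings`, `dropped` (names of
#'   zero-variance columns).
#' @export
pca_scores <- function(dataset, n_components = NULL) {
  X <- dataset$features
  if (nrow(X) < 2) stop("need >= 2 samples")
  sc <- autoscale(X)
  p <- ncol(sc$X)
  if (is.null(n_components)) n_components <- max(1L, min(nrow(X) - 1L, p))
  if (p == 0) {                      # all columns constant
    k <- n_components
    return(list(scores = matrix(0, nrow(X), k),
                explained_variance = rep(0, k), proportion = rep(0, k),
                loadings = NULL, dropped = colnames(X)[!sc$kept]))
  }
  if (n_components > p)
    stop("n_components exceeds available feature count")
  pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev[seq_len(k)]^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev,
       proportion = ev / sum(pc$sdev^2),
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       dropped = colnames(X)[!sc$kept])
}

#' Ternary (closed) compositions of analyte triads
#'
#' For each triad of analytes, divides each sample's three concentrations by
#' their sum (compositional closure), the coordinates used for ternary
#' feature-component plots. Samples whose triad sums to zero are flagged and
#' their proportions set to NA rather than fabricated.
#'
#' Default triads are the three diagnostic combinations: (EGCG, EGC, GC),
#' (EC, EGCG, EGC) and (CAF, ECG, EC).
#'
#' @param dataset An `origin_dataset`.
#' @param triads List of character vectors of length 3.
#' @return List of `triad_composition` objects: `triad`, `proportions`
#'   (sample x 3, rows summing to 1), `flagged` (logical, all-zero rows).
#' @export
fca_triads <- function(dataset,
                       triads = list(c("EGCG", "EGC", "GC"),
                                     c("EC", "EGCG", "EGC"),
                                     c("CAF", "ECG", "EC"))) {
  X <- dataset$features
  lapply(triads, function(tr) {
    if (length(tr) != 3) stop("each triad must have exactly 3 analytes")
    missing <- setdiff(tr, colnames(X))
    if (length(missing))
      stop("unknown analyte name(s): ", paste(missing, collapse = ", "))
    M <- X[, tr, drop = FALSE]
    s <- rowSums(M)
    flagged <- s == 0
    Pr <- M / s
    Pr[flagged, ] <- NA_real_
    structure(list(triad = tr, proportions = Pr, flagged = flagged),
              class = "triad_composition")
  })
}

#' Stratified random train/validation split
#'
#' Splits the dataset into disjoint, exhaustive train and validation sets.
#' By default the validation set is stratified across origins by
#' largest-remainder proportional allocation, which at the field-study sizes
#' (22/18/23 with 7 validation samples) yields the 2 FR / 2 GMEX / 3 YTS
#' composition.
#'
#' @param dataset An `origin_dataset`.
#' @param n_validation Number of validation samples (< n).
#' @param seed Integer seed.
#' @param stratified Stratify across origins (default TRUE).
#' @param strata Optional named integer vector fixing the per-origin
#'   validation counts explicitly.
#' @return List with `train` and `validation` (`origin_dataset`s) and
#'   `validation_idx` (indices into the input dataset).
#' @export
split_train_validation <- function(dataset, n_validation, seed = 1L,
                                   stratified = TRUE, strata = NULL) {
  n <- nrow(dataset$features)
  if (n_validation >= n) stop("n_validation must be < n")
  set.seed(seed)
  if (n_validation == 0) {
    idx <- integer(0)
  } else if (stratified) {
    counts <- table(dataset$labels)
    if (is.null(strata)) {
      exact <- as.numeric(counts) * n_validation / n
      base <- floor(exact)
      rem <- n_validation - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      strata <- stats::setNames(as.integer(base), names(counts))
    }
    if (any(strata > counts[names(strata)]))
      stop("origin group too small for requested stratum")
    idx <- unlist(lapply(names(strata), function(g) {
      pool <- which(dataset$labels == g)
      pool[sample.int(length(pool), strata[[g]])]
    }), use.names = FALSE)
  } else {
    idx <- sample.int(n, n_validation)
  }
  idx <- sort(idx)
  list(train = origin_subset(dataset, setdiff(seq_len(n), idx)),
       validation = origin_subset(dataset, idx),
       validation_idx = idx)
}

origin_subset <- function(dataset, idx) {
  structure(list(features = dataset$features[idx, , drop = FALSE],
                 labels = factor(dataset$labels[idx],
                                 levels = levels(dataset$labels)),
                 sample_ids = dataset$sample_ids[idx]),
            class = "origin_dataset")
}

#' Linear discriminant analysis classification
#'
#' Multiclass LDA fit on the training set (features autoscaled with
#' training-set statistics) and applied to the validation set. A singular
#' within-class scatter falls back to a ridge-regularized Mahalanobis
#' classifier (message emitted).
#'
#' @param train,validation `origin_dataset`s with the same feature columns.
#' @return A `classification_result` (confusion matrix rows = actual).
#' @export
lda_classify <- function(train, validation) {
  if (nlevels(droplevels(train$labels)) < 2)
    stop("need >= 2 classes in training data")
  sc <- autoscale(train$features, warn = FALSE)
  Xtr <- sc$X
  Xva <- autoscale(validation$features, center = sc$center,
                   scale = sc$scale, warn = FALSE)$X
  fit <- tryCatch(MASS::lda(Xtr, grouping = droplevels(train$labels)),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    pred <- stats::predict(fit, Xva)$class
  } else {
    message("singular within-class scatter; using ridge-regularized ",
            "Mahalanobis classifier")
    classes <- levels(droplevels(train$labels))
    mu <- sapply(classes, function(g)
      colMeans(Xtr[train$labels == g, , drop = FALSE]))
    Sw <- Reduce(`+`, lapply(classes, function(g) {
      Z <- sweep(Xtr[train$labels == g, , drop = FALSE], 2, mu[, g])
      crossprod(Z)
    })) / max(1, nrow(Xtr) - length(classes))
    Swr <- Sw + diag(0.01 * mean(diag(Sw)) + 1e-8, ncol(Xtr))
    Si <- solve(Swr)
    d2 <- sapply(classes, function(g) {
      Z <- sweep(Xva, 2, mu[, g])
      rowSums((Z %*% Si) * Z)
    })
    pred <- classes[apply(as.matrix(d2), 1, which.min)]
  }
  classification_result("LDA",
    make_confusion(validation$labels, pred, levels(train$labels)))
}

#' PLS-DA classification with VIP scores
#'
#' Partial least squares discriminant analysis with the latent-variable
#' count chosen by stratified 5-fold cross-validation on the training set
#' (ties broken toward fewer components). Classification uses the maximum
#' predicted class indicator. Variable importance in projection (VIP) is
#' reported for the selected model; per component, the mean squared VIP over
#' features equals 1.
#'
#' @param train,validation `origin_dataset`s.
#' @param max_lv Maximum latent variables to consider (capped at feasible
#'   rank).
#' @param seed Integer seed for the CV folds.
#' @return A `classification_result` with extra fields `vip` (named vector
#'   for the selected component count), `n_lv`, `cv_accuracy`.
#' @export
plsda_classify <- function(train, validation, max_lv = 8, seed = 1L) {
  sc <- autoscale(train$features, warn = FALSE)
  Xtr <- sc$X
  Xva <- autoscale(validation$features, center = sc$center,
                   scale = sc$scale, warn = FALSE)$X
  ytr <- droplevels(train$labels)
  n <- nrow(Xtr)
  max_lv <- min(max_lv, ncol(Xtr), n - 2)
  if (max_lv < 1) stop("max_lv exceeds the rank of the training features")

  set.seed(seed)
  nfold <- 5
  fold <- integer(n)
  for (g in levels(ytr)) {          # stratified folds
    ix <- which(ytr == g)
    fold[ix] <- sample(rep_len(seq_len(nfold), length(ix)))
  }
  cv_acc <- numeric(max_lv)
  for (f in seq_len(nfold)) {
    hold <- fold == f
    if (nlevels(droplevels(ytr[!hold])) < 2) next
    fit <- mixOmics::plsda(Xtr[!hold, , drop = FALSE], ytr[!hold],
                           ncomp = max_lv, scale = FALSE)
    pr <- stats::predict(fit, Xtr[hold, , drop = FALSE])$class$max.dist
    for (h in seq_len(max_lv))
      cv_acc[h] <- cv_acc[h] + sum(pr[, h] == as.character(ytr[hold]))
  }
  cv_acc <- cv_acc / n
  n_lv <- which.max(cv_acc)          # ties -> fewer components

  fit <- mixOmics::plsda(Xtr, ytr, ncomp = n_lv, scale = FALSE)
  vip_all <- mixOmics::vip(fit)
  vip <- vip_all[, n_lv]
  pred <- if (nrow(Xva) > 0)
    stats::predict(fit, Xva)$class$max.dist[, n_lv] else character(0)
  classification_result("PLS-DA",
    make_confusion(validation$labels, pred, levels(train$labels)),
    vip = vip, n_lv = n_lv, cv_accuracy = cv_acc[n_lv],
    cv_accuracy_by_lv = cv_acc)
}

#' The L9(3^4) orthogonal hyperparameter design
#'
#' The canonical Taguchi L9 array over the four t-SNE hyperparameters:
#' perplexity (5, 20, 50), learning rate (10, 100, 1000), iterations
#' (250, 500, 1000) and early exaggeration (4, 8, 12). Nine runs; each
#' factor's three levels appear three times each, and every ordered pair of
#' levels of any two factors occurs exactly once.
#'
#' @return Object of class `l9_design`: data frame `runs` with the actual
#'   hyperparameter values, plus `levels` (list) and `level_index` (9 x 4
#'   matrix of 1-3 level codes).
#' @export
l9_design <- function() {
  idx <- matrix(c(1, 1, 1, 1,
                  1, 2, 2, 2,
                  1, 3, 3, 3,
                  2, 1, 2, 3,
                  2, 2, 3, 1,
                  2, 3, 1, 2,
                  3, 1, 3, 2,
                  3, 2, 1, 3,
                  3, 3, 2, 1), nrow = 9, byrow = TRUE)
  levels <- list(perplexity = c(5, 20, 50),
                 learning_rate = c(10, 100, 1000),
                 iterations = c(250, 500, 1000),
                 early_exaggeration = c(4, 8, 12))
  runs <- data.frame(run = seq_len(9),
                     perplexity = levels$perplexity[idx[, 1]],
                     learning_rate = levels$learning_rate[idx[, 2]],
                     iterations = levels$iterations[idx[, 3]],
                     early_exaggeration = levels$early_exaggeration[idx[, 4]])
  colnames(idx) <- names(levels)
  structure(list(runs = runs, levels = levels, level_index = idx),
            class = "l9_design")
}

#' t-SNE embedding + random-forest classification
#'
#' Embeds all samples jointly (labels untouched) with [tsne_embed()] using
#' the correlation distance, then trains a 500-tree random forest (Gini
#' impurity) on the training samples' embedding coordinates and classifies
#' the validation samples' coordinates. Both 2D and 3D embeddings are
#' computed; the 3D one feeds the forest by default. The silhouette
#' coefficient of the true origin labels on the chosen embedding is
#' reported.
#'
#' Because t-SNE has no out-of-sample transform, validation samples are part
#' of the (unsupervised) embedding; only the forest is restricted to
#' training coordinates. This is a mild information leak inherent to the
#' protocol and is documented rather than hidden.
#'
#' @param dataset The full `origin_dataset` (train + validation).
#' @param split A split from [split_train_validation()].
#' @param hyper Named list or one-row data frame with `perplexity`,
#'   `learning_rate`, `iterations`, `early_exaggeration`.
#' @param seed Integer seed (embedding init and forest).
#' @param embedding_dims Which embedding feeds the forest: 3 (default) or 2.
#' @return A `classification_result` with `embedding_2d`, `embedding_3d`,
#'   `hyper`, and out-of-bag training accuracy `train_accuracy`.
#' @export
tsne_rf_classify <- function(dataset, split,
                             hyper = list(perplexity = 50,
                                          learning_rate = 100,
                                          iterations = 250,
                                          early_exaggeration = 12),
                             seed = 1L, embedding_dims = 3) {
  hyper <- as.list(hyper)
  X <- autoscale(dataset$features, warn = FALSE)$X
  n <- nrow(X)
  if (hyper$perplexity >= n) stop("perplexity must be < n")
  emb2 <- tsne_embed(X, dims = 2, perplexity = hyper$perplexity,
                     learning_rate = hyper$learning_rate,
                     iterations = hyper$iterations,
                     early_exaggeration = hyper$early_exaggeration,
                     metric = "correlation", seed = seed)
  emb3 <- tsne_embed(X, dims = 3, perplexity = hyper$perplexity,
                     learning_rate = hyper$learning_rate,
                     iterations = hyper$iterations,
                     early_exaggeration = hyper$early_exaggeration,
                     metric = "correlation", seed = seed + 1L)
  emb <- if (embedding_dims == 3) emb3 else emb2
  rownames(emb) <- dataset$sample_ids

  vidx <- split$validation_idx
  tidx <- setdiff(seq_len(n), vidx)
  ytr <- droplevels(dataset$labels[tidx])
  set.seed(seed)
  rf <- randomForest::randomForest(emb[tidx, , drop = FALSE], y = ytr,
                                   ntree = 500)
  pred <- if (length(vidx) > 0)
    stats::predict(rf, emb[vidx, , drop = FALSE]) else factor(character(0))
  sil <- if (nlevels(droplevels(dataset$labels)) >= 2)
    mean(cluster::silhouette(as.integer(dataset$labels),
                             stats::dist(emb))[, "sil_width"])
  else NA_real_
  classification_result("t-SNE-RF",
    make_confusion(dataset$labels[vidx], pred, levels(dataset$labels)),
    silhouette = sil,
    embedding_2d = emb2, embedding_3d = emb3, hyper = hyper,
    train_accuracy = 1 - rf$err.rate[rf$ntree, "OOB"])
}

#' Run the full L9 hyperparameter screen for t-SNE-RF
#'
#' Executes [tsne_rf_classify()] for each of the nine design runs with a
#' shared seed policy, records the validation accuracy of each run, and
#' returns the best run (ties broken to the lowest run index).
#'
#' @param dataset The full `origin_dataset`.
#' @param split A split from [split_train_validation()].
#' @param design An [l9_design()].
#' @param seed Integer seed shared across runs.
#' @return List: `best_run` (row index), `best` (its
#'   `classification_result`), `scores` (the design's `runs` table with a
#'   `validation_accuracy` column), `results` (all nine results).
#' @export
optimize_tsne_rf <- function(dataset, split, design = l9_design(),
                             seed = 1L) {
  runs <- design$runs
  results <- vector("list", nrow(runs))
  acc <- numeric(nrow(runs))
  for (r in seq_len(nrow(runs))) {
    results[[r]] <- tsne_rf_classify(dataset, split,
                                     hyper = runs[r, -1], seed = seed)
    acc[r] <- results[[r]]$accuracy
  }
  best <- which.max(acc)              # ties -> lowest index
  scores <- cbind(runs, validation_accuracy = acc)
  list(best_run = best, best = results[[best]], scores = scores,
       results = results)
}
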