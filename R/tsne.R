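# Exact t-SNE (Student-t stochastic neighbor embedding) on a precomputed
# distance matrix. Implemented in full rather than delegated so that the
# study's configuration (perplexity 50 on 63 samples, correlation distance)
# is supported: common implementations reject perplexity > (n-1)/3.
# Cost is O(n^2) per iteration - negligible at the sample sizes used here.

# Conditional-probability matrix with per-point bandwidths found by binary
# search to match the target perplexity (entropy = log2(perplexity)).
tsne_p_matrix <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (try in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0; p <- rep(0, length(di)) }
      else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) { beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else { beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding with correlation distance
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding of a
#' feature matrix, using the correlation distance `1 - cor(x_i, x_j)` between
#' sample profiles by default. Gradient descent uses the standard schedule:
#' early exaggeration of the input probabilities for the first
#' `min(100, iterations/2)` steps, momentum 0.5 switching to 0.8 after the
#' exaggeration phase, and per-coordinate adaptive gains.
#'
#' @param X Numeric matrix (samples x features), already scaled as desired.
#' @param dims Output dimensionality (2 or 3).
#' @param perplexity Effective neighborhood size; must satisfy
#'   `perplexity < n`.
#' @param learning_rate Gradient step size (eta).
#' @param iterations Total gradient-descent iterations.
#' @param early_exaggeration Factor applied to P during the exaggeration
#'   phase.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param seed Integer seed for the initial configuration.
#' @return Matrix (samples x dims) of embedding coordinates.
#' @export
tsne_embed <- function(X, dims = 2, perplexity = 30, learning_rate = 100,
                       iterations = 500, early_exaggeration = 4,
                       metric = c("correlation", "euclidean"), seed = 1L) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity >= n) stop("perplexity must be < number of samples")
  if (n < 4) stop("need at least 4 samples")
  D <- switch(metric,
    correlation = {
      if (ncol(X) < 2) stop("correlation distance needs >= 2 features")
      sds <- apply(X, 1, stats::sd)
      if (any(sds == 0)) stop("degenerate all-equal feature profile")
      1 - stats::cor(t(X))
    },
    euclidean = as.matrix(stats::dist(X)))
  P <- tsne_p_matrix(D^2, perplexity)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  exag_end <- min(100L, floor(iterations / 2))
  Pex <- P * early_exaggeration
  for (it in seq_len(iterations)) {
    Pit <- if (it <= exag_end) Pex else P
    momentum <- if (it <= exag_end) 0.5 else 0.8
    # pairwise Student-t affinities
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    flip <- sign(grad) != sign(dY)
    gains <- pmax(ifelse(flip, gains + 0.2, gains * 0.8), 0.01)
    dY <- momentum * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
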