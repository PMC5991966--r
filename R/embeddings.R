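# Low-dimensional embeddings of the ensemble coordinate matrix: PCA, FastICA
# and locally linear embedding, plus neighborhood-size selection for LLE.

new_embedding <- function(method, scores, components = NULL,
                          variance_fractions = NULL, params = list(),
                          converged = TRUE) {
  structure(list(method = method, scores = scores, components = components,
                 variance_fractions = variance_fractions, params = params,
                 converged = converged),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat("Embedding (", x$method, "): ", nrow(x$scores), " samples x ",
      ncol(x$scores), " dims\n", sep = "")
  invisible(x)
}

embedding_input <- function(ensemble) {
  if (inherits(ensemble, "EnsembleMatrix")) ensemble$coords else as.matrix(ensemble)
}

fix_sign <- function(vecs) {
  # deterministic sign convention: the largest-magnitude loading is positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  vecs
}

#' Principal component analysis of an ensemble matrix
#'
#' Column-centers the n x 3m coordinate matrix and decomposes its covariance;
#' scores are the member projections, `variance_fractions` the per-component
#' eigenvalue over the total variance. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param ensemble `EnsembleMatrix` (superposed) or plain matrix.
#' @param d Number of components, `1 <= d <= n - 1`.
#' @return An `Embedding` with `scores` (n x d), `components` (d x 3m) and
#'   `variance_fractions`.
#' @export
ensemble_pca <- function(ensemble, d) {
  X <- embedding_input(ensemble)
  n <- nrow(X)
  if (d < 1L || d > n - 1L) stop("d must be between 1 and n - 1 = ", n - 1L)
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(X)))
  ev <- s$d^2 / (n - 1L)                       # covariance eigenvalues
  total <- sum(Xc^2) / (n - 1L)
  V <- fix_sign(s$v[, seq_len(d), drop = FALSE])
  scores <- Xc %*% V
  rownames(scores) <- rownames(X)
  new_embedding("pca", scores, components = t(V),
                variance_fractions = ev[seq_len(d)] / total,
                params = list(d = d))
}

#' FastICA with a log-cosh contrast (deflationary)
#'
#' The data are whitened by PCA to `d` dimensions, then independent directions
#' are extracted one at a time by fixed-point iteration with the
#' `G(u) = log cosh(u)` contrast (an approximation to negentropy), with
#' Gram-Schmidt deflation. Scores have unit variance and are mutually
#' uncorrelated. Runs are reproducible for a fixed seed.
#'
#' @param ensemble `EnsembleMatrix` or matrix.
#' @param d Number of components (`d <= n - 1`).
#' @param seed Mandatory integer seed for the random initial directions.
#' @param tol Convergence tolerance on the change of direction.
#' @param max_iter Maximum fixed-point iterations per component.
#' @return An `Embedding`; `converged` is `FALSE` (with the partial result
#'   kept) if any component failed to converge.
#' @export
ensemble_fastica <- function(ensemble, d, seed, tol = 1e-6, max_iter = 200L) {
  X <- embedding_input(ensemble)
  n <- nrow(X)
  if (d > n - 1L) stop("d must be <= n - 1")
  if (missing(seed)) stop("seed is required")
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  pos <- s$d > max(s$d) * 1e-9
  if (sum(pos) < d) stop("data rank ", sum(pos), " is below d = ", d)
  # whitened signals: n x d with identity covariance
  Z <- sqrt(n - 1L) * s$u[, which(pos)[seq_len(d)], drop = FALSE]
  K <- s$v[, which(pos)[seq_len(d)], drop = FALSE] %*%
    diag(sqrt(n - 1L) / s$d[which(pos)[seq_len(d)]], d, d)  # 3m x d whitening

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- matrix(0, d, d)
  converged <- TRUE
  for (i in seq_len(d)) {
    w <- stats::rnorm(d); w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      u <- as.vector(Z %*% w)
      g <- tanh(u)
      gp <- 1 - g^2
      w_new <- colMeans(Z * g) - mean(gp) * w
      if (i > 1L) {             # deflate against previous components
        Wp <- W[seq_len(i - 1L), , drop = FALSE]
        w_new <- w_new - as.vector(t(Wp) %*% (Wp %*% w_new))
      }
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12) break
      w_new <- w_new / nw
      delta <- 1 - abs(sum(w_new * w))
      w <- w_new
      if (delta < tol) { ok <- TRUE; break }
    }
    if (!ok) converged <- FALSE
    W[i, ] <- w
  }
  S <- Z %*% t(W)
  # deterministic sign: largest-magnitude score of each component positive
  S <- fix_sign(S)
  rownames(S) <- rownames(X)
  comp <- t(K %*% t(W))        # unmixing directions in original space
  new_embedding("fastica", S, components = comp,
                params = list(d = d, seed = seed, tol = tol,
                              max_iter = max_iter),
                converged = converged)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Locally linear embedding
#'
#' Each sample is reconstructed as a constrained least-squares combination of
#' its `k` nearest neighbors (weights summing to one; the neighbor Gram matrix
#' is regularized by `reg * trace` when it is rank-deficient). The embedding
#' is given by the bottom `d` non-trivial eigenvectors of
#' `(I - W)' (I - W)`, scaled to unit variance per dimension.
#'
#' @param ensemble `EnsembleMatrix` or matrix.
#' @param k Number of neighbors (`k < n`).
#' @param d Embedding dimensionality (`d < n`).
#' @param reg Gram-matrix regularization factor.
#' @return An `Embedding` with `scores` (n x d) and per-sample `weights`
#'   stored in `params`.
#' @export
ensemble_lle <- function(ensemble, k, d, reg = 1e-3) {
  X <- embedding_input(ensemble)
  n <- nrow(X)
  if (k >= n) stop("k must be < n")
  if (d >= n) stop("d must be < n")
  Dm <- as.matrix(stats::dist(X))
  nbrs <- t(vapply(seq_len(n), function(i) {
    order(Dm[i, ])[-1L][seq_len(k)]
  }, integer(k)))
  # neighbor graph must be connected for a meaningful global embedding
  g <- igraph::graph_from_edgelist(
    cbind(rep(seq_len(n), each = k), as.vector(t(nbrs))), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("neighbor graph is disconnected (", comp$no, " components): ",
         paste(tapply(seq_len(n), comp$membership, function(ix)
           paste0("{", paste(head(ix, 5), collapse = ","), "}")),
           collapse = " "))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Ni <- nbrs[i, ]
    Gz <- sweep(X[Ni, , drop = FALSE], 2, X[i, ])
    G <- tcrossprod(Gz)
    tr <- sum(diag(G))
    if (tr > 0) G <- G + diag(reg * tr, k)
    else G <- G + diag(reg, k)
    w <- solve(G, rep(1, k))
    W[i, Ni] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)[seq(2L, d + 1L)]      # drop the constant eigenvector
  Y <- e$vectors[, idx, drop = FALSE] * sqrt(n)
  Y <- fix_sign(Y)
  rownames(Y) <- rownames(X)
  new_embedding("lle", Y, params = list(k = k, d = d, reg = reg, weights = W))
}

#' Select the LLE neighborhood size
#'
#' Re-embeds the data for every candidate `k` and keeps the one maximizing the
#' Pearson correlation between the high-dimensional and the embedded pairwise
#' distance matrices (a residual-variance style criterion). Deterministic;
#' ties go to the smaller `k`.
#'
#' @param ensemble `EnsembleMatrix` or matrix.
#' @param k_candidates Integer candidates, all `< n`.
#' @param d Embedding dimensionality used for the evaluation.
#' @return The selected `k`, with the per-candidate criterion values in
#'   attribute `criterion`.
#' @export
select_lle_k <- function(ensemble, k_candidates, d = 2L) {
  X <- embedding_input(ensemble)
  k_candidates <- as.integer(k_candidates)
  valid <- k_candidates[k_candidates >= 1L & k_candidates < nrow(X)]
  if (length(valid) == 0L) stop("no valid k candidates (need 1 <= k < n)")
  d_hi <- stats::dist(X)
  # candidates whose neighbor graph is disconnected are unusable and score NA
  crit <- vapply(valid, function(k) {
    tryCatch({
      emb <- ensemble_lle(X, k = k, d = d)
      stats::cor(as.vector(d_hi), as.vector(stats::dist(emb$scores)))
    }, error = function(e) NA_real_)
  }, numeric(1))
  names(crit) <- valid
  if (all(is.na(crit)))
    stop("no candidate k yields a usable (connected) embedding")
  best <- valid[which.max(crit)]
  attr(best, "criterion") <- crit
  best
}
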