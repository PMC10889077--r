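# Internal numeric helpers shared across modules.

# Randomized SVD PCA scores (Halko-style, with power iterations).
# Column-centering is applied implicitly so X can stay un-copied.
# Deterministic under `seed`.
.rsvd_scores <- function(X, d, seed = 1L, n_iter = 2L, n_oversample = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); G <- ncol(X)
  d <- max(1L, min(d, n - 1L, G))
  p <- min(d + n_oversample, G, n)
  cm <- colMeans(X)
  set.seed(seed)
  Omega <- matrix(rnorm(G * p), G, p)
  Y <- X %*% Omega - tcrossprod(rep(1, n), drop(crossprod(cm, Omega)))
  Q <- qr.Q(qr(Y))
  for (i in seq_len(n_iter)) {
    Z <- crossprod(X, Q) - tcrossprod(cm, colSums(Q))
    Z <- qr.Q(qr(Z))
    Y <- X %*% Z - tcrossprod(rep(1, n), drop(crossprod(cm, Z)))
    Q <- qr.Q(qr(Y))
  }
  B <- crossprod(Q, X) - tcrossprod(colSums(Q), cm)
  sv <- svd(B, nu = p, nv = 0)
  # sign convention: largest-magnitude loading positive, for reproducibility
  scores <- (Q %*% sv$u)[, seq_len(d), drop = FALSE] *
    rep(sv$d[seq_len(d)], each = n)
  flip <- vapply(seq_len(d), function(j) {
    v <- scores[, j]; if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores * rep(flip, each = n)
}

# Squared Euclidean cross-distances between row sets (dense, blockless).
.dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# k nearest neighbors of each row of `query` among rows of `ref`
# (self excluded when query is ref itself). Returns list(index, dist),
# each n_query x k, computed in row blocks to bound memory.
.knn_index <- function(ref, k, query = NULL, block = 1024L) {
  self <- is.null(query)
  if (self) query <- ref
  nq <- nrow(query)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  starts <- seq(1L, nq, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, nq)
    d2 <- .dist2(query[rows, , drop = FALSE], ref)
    if (self) d2[cbind(seq_along(rows), rows)] <- Inf
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  list(index = idx, dist = dst)
}

# Cosine-normalized rows (unit L2 norm); zero rows left as zero.
.cosine_normalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

# Deterministic per-stage seed derivation from one base seed, so stages can
# be rerun in isolation reproducibly.
.derive_seed <- function(seed, stage) {
  ints <- utf8ToInt(stage)
  h <- sum(ints * seq_along(ints))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
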