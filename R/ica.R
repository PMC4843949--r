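# Symmetric FastICA with tanh contrast and deterministic seeded
# initialization. Whitening uses a small ridge so that rank-deficient
# inputs (e.g. common-average-referenced data) still decompose into
# n_comp components.
#
# X: channels x samples (centered internally). Returns list with
# S (components x samples source time courses), A (channels x components
# mixing matrix with X ~ A %*% S + rowmeans), and the unmixing pieces.
fastica_decompose <- function(X, n_comp = nrow(X), max_iter = 60,
                              tol = 1e-5, seed = 1, ridge = 1e-8,
                              est_subsample = NULL) {
  if (is.null(est_subsample)) est_subsample <- max(1, ceiling(ncol(X) / 25000))
  nch <- nrow(X)
  if (n_comp > nch) stop("n_comp exceeds channel count")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  C <- C + diag(ridge * sum(diag(C)) / nch, nch)
  e <- eigen(C, symmetric = TRUE)
  d <- pmax(e$values[seq_len(n_comp)], ridge * sum(e$values))
  K <- diag(1 / sqrt(d), n_comp) %*% t(e$vectors[, seq_len(n_comp)])
  Z <- K %*% Xc
  # the fixed-point iteration runs on a regular time subsample; the final
  # unmixing is applied to the full data
  Ze <- if (est_subsample > 1) {
    Z[, seq(1, ncol(Z), by = est_subsample), drop = FALSE]
  } else {
    Z
  }
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- with_local_seed(seed, {
    sym_orth(matrix(stats::rnorm(n_comp * n_comp), n_comp))
  })
  nT <- ncol(Ze)
  for (it in seq_len(max_iter)) {
    U <- W %*% Ze
    GU <- tanh(U)
    W1 <- GU %*% t(Ze) / nT - diag(rowMeans(1 - GU^2)) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- e$vectors[, seq_len(n_comp)] %*% diag(sqrt(d), n_comp) %*% t(W)
  list(S = S, A = A, W = W, K = K, center = mu, iterations = it,
       converged = delta < tol)
}
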