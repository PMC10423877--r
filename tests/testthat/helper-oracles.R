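# Independent oracles used to cross-check the package's fits.  These are
# deliberately written via different algorithms / code paths than R/.

# absolute cosine similarity
abs_cos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# sign-align columns of B to A, then return max abs difference
max_diff_signed <- function(A, B) {
  stopifnot(dim(A) == dim(B))
  for (j in seq_len(ncol(B))) {
    if (sum(A[, j] * B[, j]) < 0) B[, j] <- -B[, j]
  }
  max(abs(A - B))
}

rand_block <- function(n, p, seed, prefix = "V") {
  set.seed(seed)
  data_block(matrix(rnorm(n * p), n, p),
             sample_ids = paste0("S", seq_len(n)),
             variable_names = paste0(prefix, seq_len(p)))
}

# CCA oracle: canonical correlations as square roots of the eigenvalues of
# Sx^{-1} Sxy Sy^{-1} Syx (dense generalized-eigenproblem formulation,
# explicit inverses - numerically cruder than the package solver on
# purpose).
oracle_cca_correlations <- function(X, Y) {
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  n <- nrow(Xc)
  Sx <- crossprod(Xc) / (n - 1)
  Sy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sx) %*% Sxy %*% solve(Sy) %*% t(Sxy)
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(min(ncol(Xc), ncol(Yc)))], 0))
}

# Classical iterative NIPALS PLS2 (u-t exchange form), X-deflation only.
# Independent of the package's SVD-based solve.
oracle_pls2 <- function(X, Y, k, tol = 1e-13, max_iter = 10000) {
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yc <- scale(as.matrix(Y), scale = FALSE)
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Q <- matrix(0, m, k); Tm <- matrix(0, n, k)
  Xd <- Xc
  for (c in seq_len(k)) {
    u <- Yc[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      t <- Xd %*% w
      q <- crossprod(Yc, t) / sum(t^2)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    t <- as.numeric(t)
    p_load <- as.numeric(crossprod(Xd, t)) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p_load)
    W[, c] <- w; P[, c] <- p_load
    Q[, c] <- as.numeric(crossprod(Yc, t)) / sum(t^2)
    Tm[, c] <- t
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(W = W, P = P, Q = Q, T = Tm, B = B)
}

# Normal-equations residualization oracle (explicit inverse).
oracle_residualize <- function(values, design) {
  H <- design %*% solve(crossprod(design)) %*% t(design)
  values - H %*% values
}

# Empirically whiten a block: sample covariance of the result is exactly
# the identity.
whiten_block <- function(block) {
  v <- scale(block$values, scale = FALSE)
  S <- crossprod(v) / (nrow(v) - 1)
  e <- eigen(S, symmetric = TRUE)
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  data_block(v %*% W, block$sample_ids, block$variable_names)
}

# tiny deterministic two-block dataset with some cross-block signal
toy_blocks <- function(n = 20, p = 3, m = 2, seed = 42) {
  set.seed(seed)
  z <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p) + z
  Y <- matrix(rnorm(n * m), n, m) + 0.8 * z
  list(X = data_block(X, paste0("S", 1:n), paste0("X", 1:p)),
       Y = data_block(Y, paste0("S", 1:n), paste0("Y", 1:m)))
}
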