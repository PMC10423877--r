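# Cross-decomposition fits: CCA, PLSC (PLS-SVD), PLSR (PLS2).
# All three share the cross_fit container: weight matrices U (p x k) and
# V (m x k), score matrices T = X U and S = Y V, a per-component
# association value, and structure-coefficient (loading) matrices.

check_blocks <- function(x, y) {
  if (!inherits(x, "data_block") || !inherits(y, "data_block"))
    stop_validation("fits expect data_block inputs")
  if (nrow(x$values) != nrow(y$values) ||
      !identical(x$sample_ids, y$sample_ids))
    stop_validation("blocks have different samples or sample order; run align_samples()/preprocess_blocks() first")
  if (nrow(x$values) < 3L)
    stop_validation("need at least 3 samples")
}

center_cols <- function(v) sweep(v, 2, colMeans(v))

default_k <- function(p, m) min(p, m, 4L)

# Deterministic sign convention: flip each component jointly so the
# largest-|entry| of the y-side weight vector is positive.
apply_sign_convention <- function(U, V, flip_extra = list()) {
  k <- ncol(V)
  signs <- numeric(k)
  for (c in seq_len(k)) {
    i <- which.max(abs(V[, c]))
    signs[c] <- if (V[i, c] < 0) -1 else 1
  }
  flip <- function(M) sweep(M, 2, signs, `*`)
  out <- list(U = flip(U), V = flip(V), signs = signs)
  out$extra <- lapply(flip_extra, flip)
  out
}

new_cross_fit <- function(method, X, Y, U, V, assoc, scoresT = NULL,
                          scoresS = NULL, details = list(),
                          diagnostics = list()) {
  Xc <- center_cols(X$values)
  Yc <- center_cols(Y$values)
  k <- ncol(U)
  sc <- apply_sign_convention(U, V)
  U <- sc$U
  V <- sc$V
  Tm <- if (is.null(scoresT)) Xc %*% U else sweep(scoresT, 2, sc$signs, `*`)
  Sm <- if (is.null(scoresS)) Yc %*% V else sweep(scoresS, 2, sc$signs, `*`)
  for (nm in names(details))
    if (nm %in% c("W", "P", "Q"))
      details[[nm]] <- sweep(details[[nm]], 2, sc$signs, `*`)
  comp <- paste0("C", seq_len(k))
  dimnames(U) <- list(X$variable_names, comp)
  dimnames(V) <- list(Y$variable_names, comp)
  dimnames(Tm) <- list(X$sample_ids, comp)
  dimnames(Sm) <- list(Y$sample_ids, comp)
  diagnostics$close_singular_values <-
    if (k > 1) any(abs(diff(assoc)) < 1e-10) else FALSE
  fit <- structure(
    list(method = method, k = k, U = U, V = V, T = Tm, S = Sm,
         assoc = setNames(as.numeric(assoc), comp),
         x_variables = X$variable_names, y_variables = Y$variable_names,
         sample_ids = X$sample_ids, details = details,
         diagnostics = diagnostics),
    class = "cross_fit")
  ld <- structure_coefficients(fit, X, Y)
  fit$x_loadings <- ld$x_loadings
  fit$y_loadings <- ld$y_loadings
  fit
}

#' @export
print.cross_fit <- function(x, ...) {
  cat(sprintf("<cross_fit> method=%s, k=%d, n=%d, p=%d, m=%d\n",
              x$method, x$k, length(x$sample_ids),
              length(x$x_variables), length(x$y_variables)))
  cat("  assoc:", paste(format(round(x$assoc, 4)), collapse = "  "), "\n")
  invisible(x)
}

#' Canonical correlation analysis
#'
#' Finds successive weight pairs `(u, v)` maximizing the Pearson
#' correlation of the scores `Xu` and `Yv`, each pair's scores being
#' uncorrelated with all earlier scores within its block.  Solved as the
#' SVD of the whitened cross-covariance
#' `Sx^{-1/2} Sxy Sy^{-1/2}` with symmetric inverse square roots; because
#' of the whitening, the result is invariant to any invertible linear
#' re-mixing within a block.
#'
#' @param X,Y preprocessed [data_block()]s with identical samples.
#' @param k number of components, at most `min(p, m)`; defaults to
#'   `min(p, m, 4)`.
#' @param ridge regularization added to the within-block covariances
#'   before inversion: `0` (none; singular covariance is then an error),
#'   `"auto"` (`1e-8 * trace / dim` per block), or a non-negative number.
#' @return a `cross_fit` with `assoc` = canonical correlations (descending,
#'   in `[0, 1]`).
#' @export
fit_cca <- function(X, Y, k = NULL, ridge = 0) {
  check_blocks(X, Y)
  Xc <- center_cols(X$values)
  Yc <- center_cols(Y$values)
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  k <- as.integer(k %||% default_k(p, m))
  if (k < 1L || k > min(p, m))
    stop_validation("k must be between 1 and min(p, m) = %d", min(p, m))
  Sx <- crossprod(Xc) / (n - 1)
  Sy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  inv_sqrt <- function(S, label) {
    d <- nrow(S)
    eps <- if (identical(ridge, "auto")) 1e-8 * sum(diag(S)) / d
           else as.numeric(ridge)
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values + eps
    if (min(vals) <= max(vals) * 1e-12 || min(vals) <= 0)
      stop_numerical(
        "within-block covariance of %s is (near-)singular; refit with ridge = \"auto\" or a positive ridge",
        label)
    e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  Wx <- inv_sqrt(Sx, "X")
  Wy <- inv_sqrt(Sy, "Y")
  sv <- svd(Wx %*% Sxy %*% Wy)
  U <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  V <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  assoc <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  new_cross_fit("CCA", X, Y, U, V, assoc,
                diagnostics = list(ridge = ridge,
                                   all_singular_values = sv$d))
}

#' Partial least squares correlation (PLS-SVD)
#'
#' All components come from a single SVD of the cross-covariance matrix
#' `X'Y / (n - 1)`: `U` and `V` are the top-`k` left/right singular
#' vectors (unit norm) and `assoc` the corresponding singular values,
#' i.e. the maximized covariances `cov(Xu, Yv)`.  No deflation is
#' applied.
#'
#' @inheritParams fit_cca
#' @return a `cross_fit` with `assoc` = singular values of the
#'   cross-covariance (descending).
#' @export
fit_plsc <- function(X, Y, k = NULL) {
  check_blocks(X, Y)
  Xc <- center_cols(X$values)
  Yc <- center_cols(Y$values)
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  k <- as.integer(k %||% default_k(p, m))
  if (k < 1L || k > min(p, m))
    stop_validation("k must be between 1 and min(p, m) = %d", min(p, m))
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  sv <- svd(Sxy)
  rank <- sum(sv$d > max(sv$d[1], 0) * 1e-12)
  if (k > rank)
    stop_validation("k = %d exceeds the rank of the cross-covariance (%d)",
                    k, rank)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  new_cross_fit("PLSC", X, Y, U, V, sv$d[seq_len(k)],
                diagnostics = list(all_singular_values = sv$d))
}

#' Partial least squares regression (PLS2)
#'
#' Asymmetric, predictive PLS (PLS2): per component the X-weight is the
#' leading left singular vector of the current (deflated) cross-covariance
#' - computed by a deterministic dense SVD, which is the exact fixed
#' point of the classical NIPALS weight iteration (see the methods
#' vignette for why the iterative solve is not used); `X` is then
#' deflated by regression on its score.  `Y` is not deflated.  The stored `U` are the rotation
#' weights `W (P'W)^{-1}`, so the identity `T = X U` holds for the
#' deflation-defined scores; the raw per-component weights are kept in
#' `details$W`.  The coefficient matrix `details$B` (`p x m`) gives
#' predictions `X_new B` (on centered data; [predict.cross_fit()] handles
#' the centering).
#'
#' @inheritParams fit_cca
#' @return a `cross_fit` with `assoc` = sample covariance of each paired
#'   score column (comparable across methods while respecting the PLSR
#'   objective).
#' @export
fit_plsr <- function(X, Y, k = NULL) {
  check_blocks(X, Y)
  Xc <- center_cols(X$values)
  Yc <- center_cols(Y$values)
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- ncol(Yc)
  k <- as.integer(k %||% default_k(p, m))
  rank_x <- qr(Xc)$rank
  if (k < 1L || k > rank_x)
    stop_validation("k must be between 1 and rank(X) = %d", rank_x)
  W <- matrix(0, p, k)
  P <- matrix(0, p, k)
  Q <- matrix(0, m, k)
  Tm <- matrix(0, n, k)
  Vy <- matrix(0, m, k)
  Xd <- Xc
  for (c in seq_len(k)) {
    M <- crossprod(Xd, Yc) / (n - 1)
    sv <- svd(M, nu = 1, nv = 0)
    if (sv$d[1] <= 0)
      stop_numerical("cross-covariance vanished at component %d", c)
    w <- as.numeric(sv$u[, 1])
    # deterministic provisional sign: align with the first response
    # column's cross-covariance (the classical NIPALS starting vector)
    ref <- sum(w * M[, 1])
    if (ref < 0 || (ref == 0 && w[which(w != 0)[1]] < 0)) w <- -w
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    if (tt <= 0)
      stop_numerical("zero score at component %d (rank exhausted)", c)
    p_load <- as.numeric(crossprod(Xd, t)) / tt
    q <- as.numeric(crossprod(Yc, t)) / tt
    Xd <- Xd - tcrossprod(t, p_load)
    W[, c] <- w
    P[, c] <- p_load
    Q[, c] <- q
    Tm[, c] <- t
    v <- as.numeric(crossprod(M, w))      # y-side weight direction
    nv <- sqrt(sum(v^2))
    Vy[, c] <- if (nv > 0) v / nv else q / sqrt(sum(q^2))
  }
  PW <- crossprod(P, W)                   # unit upper triangular
  R <- W %*% backsolve(PW, diag(k))       # rotations: Tm = Xc %*% R
  B <- tcrossprod(R, Q)                   # p x m coefficients
  Sm <- Yc %*% Vy
  assoc <- colSums(Tm * Sm) / (n - 1)
  new_cross_fit("PLSR", X, Y, R, Vy, assoc, scoresT = Tm, scoresS = Sm,
                details = list(W = W, P = P, Q = Q, B = B,
                               x_means = colMeans(X$values),
                               y_means = colMeans(Y$values),
                               deflated_x = Xd),
                diagnostics = list())
}

#' Predict responses from a PLSR fit
#'
#' @param object a `cross_fit` with `method == "PLSR"`.
#' @param newdata [data_block()] or numeric matrix with the fit's X
#'   variables.
#' @param ... unused.
#' @return numeric matrix of predicted Y values.
#' @export
predict.cross_fit <- function(object, newdata, ...) {
  if (object$method != "PLSR")
    stop_validation("predict() is defined for PLSR fits only")
  Xn <- if (inherits(newdata, "data_block")) newdata$values else as.matrix(newdata)
  if (ncol(Xn) != length(object$x_variables))
    stop_validation("newdata has %d columns; fit expects %d",
                    ncol(Xn), length(object$x_variables))
  B <- object$details$B
  # details$B is sign-invariant under the component sign convention
  sweep(Xn, 2, object$details$x_means) %*% B +
    matrix(object$details$y_means, nrow(Xn), length(object$y_variables),
           byrow = TRUE)
}

#' Fit one method by name
#'
#' @param X,Y preprocessed [data_block()]s.
#' @param method `"CCA"`, `"PLSC"` or `"PLSR"` (case-insensitive).
#' @param k number of components.
#' @param ... passed to the specific fit function.
#' @return a `cross_fit`.
#' @export
fit_method <- function(X, Y, method, k = NULL, ...) {
  switch(toupper(method),
         CCA = fit_cca(X, Y, k = k, ...),
         PLSC = fit_plsc(X, Y, k = k, ...),
         PLSR = fit_plsr(X, Y, k = k, ...),
         stop_validation("unknown method '%s' (use CCA, PLSC or PLSR)", method))
}

#' Structure coefficients (loadings)
#'
#' The structure coefficient of variable `j` on component `c` is the
#' Pearson correlation between the observed variable and its own block's
#' latent score for that component - the quantity plotted when
#' interpreting components, and the basis of all cross-method
#' comparisons in this package.
#'
#' @param fit a `cross_fit` produced from these blocks.
#' @param X,Y the [data_block()]s the fit was computed on.
#' @return list with `x_loadings` (`p x k`) and `y_loadings` (`m x k`);
#'   every entry lies in `[-1, 1]`.
#' @export
structure_coefficients <- function(fit, X, Y) {
  if (!identical(fit$x_variables, X$variable_names) ||
      !identical(fit$y_variables, Y$variable_names))
    stop_validation("blocks do not match the fit's variables")
  if (any(apply(fit$T, 2, sd) == 0) || any(apply(fit$S, 2, sd) == 0))
    stop_validation("degenerate component: a score column has zero variance")
  list(x_loadings = cor(X$values, fit$T),
       y_loadings = cor(Y$values, fit$S))
}
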