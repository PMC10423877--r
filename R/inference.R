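# Permutation-based component significance and explained variance.

#' Per-component score correlation
#'
#' Element `c` is the Pearson correlation between the paired latent score
#' columns `T[, c]` and `S[, c]`.  For CCA this equals the canonical
#' correlation; for the PLS methods it is the correlation attained by the
#' covariance-maximizing weights, and is the statistic fed to the
#' permutation test so all three methods are compared on the same axis.
#'
#' @param fit a `cross_fit`.
#' @return named numeric vector of length `k`.
#' @export
component_rho <- function(fit) {
  k <- fit$k
  out <- setNames(numeric(k), colnames(fit$T))
  for (c in seq_len(k)) {
    if (sd(fit$T[, c]) == 0 || sd(fit$S[, c]) == 0)
      stop_validation("constant score column in component %d", c)
    out[c] <- cor(fit$T[, c], fit$S[, c])
  }
  out
}

#' Permutation test of component significance
#'
#' Fits the requested method on the observed blocks, then `B` times on
#' `(X, Y*)` where `Y*` has its rows permuted by a fresh uniform random
#' permutation (X untouched), refitting the model from scratch each time
#' and recording every component's score correlation.  P-values use the
#' add-one convention `p_c = (1 + #\{null >= observed\}) / (1 + B)`, so
#' `p >= 1/(B+1)` always; with `B = 1000` the smallest attainable p-value
#' is ~0.001.  The statistic for component `c` of a permuted fit is that
#' fit's own component `c` (no re-matching across permutations).
#'
#' Covariate residualization must happen before calling this function
#' (see [preprocess_blocks()]); permuting the residualized `Y` preserves
#' exchangeability under the null of no X-Y coupling.
#'
#' @param X,Y preprocessed [data_block()]s.
#' @param method `"CCA"`, `"PLSC"` or `"PLSR"`.
#' @param k number of components (default `min(p, m, 4)`).
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the single permutation RNG stream.
#' @param ... passed to the fit function (e.g. `ridge` for CCA).
#' @return object of class `permutation_report`: `method`, `B`, `seed`,
#'   `observed_rho` (length `k`), `null_rho` (`B x k`), `p_values`,
#'   `explained_variance` (per component, per block) and the observed
#'   `fit`.
#' @export
permutation_test <- function(X, Y, method, k = NULL, B = 1000L, seed = 1L,
                             ...) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L)
    stop_validation("B must be a positive integer (p-values are undefined at B = 0)")
  method <- toupper(method)
  if (!method %in% c("CCA", "PLSC", "PLSR"))
    stop_validation("unknown method '%s'", method)
  check_blocks(X, Y)
  fit <- fit_method(X, Y, method, k = k, ...)
  k <- fit$k
  observed <- component_rho(fit)
  n <- nrow(X$values)
  null_rho <- matrix(NA_real_, B, k,
                     dimnames = list(NULL, names(observed)))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    Yp <- data_block(Y$values[idx, , drop = FALSE],
                     sample_ids = Y$sample_ids,
                     variable_names = Y$variable_names)
    null_rho[b, ] <- component_rho(fit_method(X, Yp, method, k = k, ...))
  }
  p <- (1 + colSums(sweep(null_rho, 2, observed, `>=`))) / (1 + B)
  structure(list(method = method, B = B, seed = as.integer(seed), k = k,
                 observed_rho = observed, null_rho = null_rho,
                 p_values = p,
                 explained_variance = explained_variance(fit, X, Y),
                 fit = fit),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> method=%s, B=%d, seed=%d\n",
              x$method, x$B, x$seed))
  print(data.frame(component = names(x$observed_rho),
                   rho = round(x$observed_rho, 4),
                   p = signif(x$p_values, 4),
                   ev_x = round(x$explained_variance$x, 4),
                   ev_y = round(x$explained_variance$y, 4),
                   row.names = NULL))
  invisible(x)
}

#' Per-component explained variance
#'
#' Fraction of each block's total variance captured when its variables
#' are reconstructed from a single score column: for component `c`,
#' `sum_j loading_{jc}^2 var_j / sum_j var_j` - identical to one minus
#' the residual variance after regressing every variable on that score.
#' For fits with within-block orthogonal scores (CCA, PLSR's X side) the
#' fractions add over components and reach 1 at `k = rank`.
#'
#' @param fit a `cross_fit`.
#' @param X,Y the blocks the fit was computed on.
#' @return list with numeric vectors `x` and `y` (length `k`, each entry
#'   in `[0, 1]`).
#' @export
explained_variance <- function(fit, X, Y) {
  ld <- structure_coefficients(fit, X, Y)
  frac <- function(loadings, vals) {
    v <- apply(vals, 2, var)
    as.numeric(colSums(loadings^2 * v) / sum(v))
  }
  list(x = setNames(frac(ld$x_loadings, X$values), colnames(fit$T)),
       y = setNames(frac(ld$y_loadings, Y$values), colnames(fit$S)))
}
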