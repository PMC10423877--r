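# Cross-method convergence/divergence: quantitative component alignment.

#' Align components of two fits
#'
#' Matches components across two fits on the same variable sets by greedy
#' maximum |cosine| of the concatenated (brain + behavior) loading
#' vectors, highest first, each component matched at most once.  The
#' reported cosine is non-negative; `sign` records the flip that aligns
#' the matched pair.  Greedy (rather than optimal-assignment) matching is
#' used deliberately: with k <= 4 the difference is immaterial and the
#' procedure is easy to audit.  Ties in |cosine| are broken by the
#' smaller component index of `fit_a`, then of `fit_b`.
#'
#' @param fit_a,fit_b `cross_fit` objects over identical variables.
#' @return data.frame of class `component_alignment` with columns
#'   `comp_a`, `comp_b`, `cosine`, `sign`; the full signed cosine matrix
#'   is kept in attribute `cosines`.
#' @export
align_components <- function(fit_a, fit_b) {
  if (!identical(fit_a$x_variables, fit_b$x_variables) ||
      !identical(fit_a$y_variables, fit_b$y_variables))
    stop_validation("fits have different variable names or order")
  la <- rbind(fit_a$x_loadings, fit_a$y_loadings)
  lb <- rbind(fit_b$x_loadings, fit_b$y_loadings)
  unit <- function(M) sweep(M, 2, sqrt(colSums(M^2)), `/`)
  C <- crossprod(unit(la), unit(lb))
  dimnames(C) <- list(colnames(fit_a$T), colnames(fit_b$T))
  ka <- ncol(la)
  kb <- ncol(lb)
  A <- abs(C)
  used_a <- logical(ka)
  used_b <- logical(kb)
  rows <- list()
  for (step in seq_len(min(ka, kb))) {
    best <- -1
    bi <- bj <- 0L
    for (i in seq_len(ka)) {
      if (used_a[i]) next
      for (j in seq_len(kb)) {
        if (used_b[j]) next
        if (A[i, j] > best + 1e-15) { best <- A[i, j]; bi <- i; bj <- j }
      }
    }
    used_a[bi] <- TRUE
    used_b[bj] <- TRUE
    rows[[step]] <- data.frame(comp_a = bi, comp_b = bj,
                               cosine = abs(C[bi, bj]),
                               sign = if (C[bi, bj] < 0) -1 else 1)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$comp_a), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, cosines = C,
            methods = c(fit_a$method, fit_b$method),
            class = c("component_alignment", "data.frame"))
}

#' Compare several fitted methods
#'
#' Builds the cross-method report: per-method counts of significant
#' components at level `alpha`, all pairwise component alignments (on
#' loadings, the scale-comparable quantity), and the dominant behavior
#' dimension - `argmax |y_loading|` - of every component, flagged by
#' significance.
#'
#' @param fits list of `cross_fit`s on identical blocks.
#' @param reports list of [permutation_test()] reports, one per fit, in
#'   the same order (matching `method` tags).
#' @param alpha significance level (default 0.05).
#' @return object of class `comparison_report` with elements `methods`,
#'   `alpha`, `n_significant`, `significant` (logical matrix
#'   method x component), `dominant_dimension` (character matrix),
#'   `alignments` (named list of [align_components()] results).
#' @export
compare_methods <- function(fits, reports, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop_validation("alpha must lie in [0, 1]")
  if (length(fits) != length(reports))
    stop_validation("need one permutation report per fit")
  methods <- vapply(fits, `[[`, character(1), "method")
  for (i in seq_along(fits)) {
    if (!identical(fits[[i]]$method, reports[[i]]$method))
      stop_validation("fit %d is %s but its report is %s",
                      i, fits[[i]]$method, reports[[i]]$method)
    if (!identical(fits[[i]]$x_variables, fits[[1]]$x_variables) ||
        !identical(fits[[i]]$y_variables, fits[[1]]$y_variables))
      stop_validation("all fits must share the same variable sets")
  }
  if (anyDuplicated(methods))
    stop_validation("duplicated method tags in fits")
  kmax <- max(vapply(fits, `[[`, integer(1), "k"))
  sig <- matrix(NA, length(fits), kmax,
                dimnames = list(methods, paste0("C", seq_len(kmax))))
  dom <- matrix(NA_character_, length(fits), kmax,
                dimnames = dimnames(sig))
  for (i in seq_along(fits)) {
    k <- fits[[i]]$k
    sig[i, seq_len(k)] <- reports[[i]]$p_values < alpha
    dom[i, seq_len(k)] <- fits[[i]]$y_variables[
      apply(abs(fits[[i]]$y_loadings), 2, which.max)]
  }
  alignments <- list()
  if (length(fits) > 1) {
    for (i in seq_len(length(fits) - 1)) {
      for (j in seq(i + 1, length(fits))) {
        alignments[[paste(methods[i], methods[j], sep = "_vs_")]] <-
          align_components(fits[[i]], fits[[j]])
      }
    }
  }
  structure(list(methods = methods, alpha = alpha,
                 n_significant = setNames(rowSums(sig, na.rm = TRUE), methods),
                 significant = sig, dominant_dimension = dom,
                 p_values = lapply(setNames(reports, methods), `[[`, "p_values"),
                 observed_rho = lapply(setNames(reports, methods), `[[`,
                                       "observed_rho"),
                 alignments = alignments),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> alpha=%g\n", x$alpha))
  cat("significant components per method:\n")
  print(x$n_significant)
  cat("dominant behavior dimension per component:\n")
  print(x$dominant_dimension, quote = FALSE)
  for (nm in names(x$alignments)) {
    cat(nm, "matched |cosines|:",
        paste(format(round(x$alignments[[nm]]$cosine, 3)), collapse = "  "),
        "\n")
  }
  invisible(x)
}
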