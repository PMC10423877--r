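#' Encode a confound table as a regression design matrix
#'
#' Builds the fixed-effects design used for covariate removal: an
#' intercept, numeric covariates as-is, and reference-level dummy coding
#' for categorical covariates (one indicator per level, dropping the
#' lexicographically first level).  The encoded matrix must be of full
#' column rank; exact collinearity is reported with the offending columns
#' named.
#'
#' @param confounds a [confound_table()].
#' @return numeric matrix of class `design_matrix`, `n x (1 + d)`, with an
#'   attribute `columns` (data.frame of covariate and level per column).
#' @export
encode_confounds <- function(confounds) {
  if (!inherits(confounds, "confound_table"))
    stop_validation("encode_confounds() expects a confound_table")
  n <- length(confounds$sample_ids)
  cols <- list(`(Intercept)` = rep(1, n))
  meta <- data.frame(covariate = "(Intercept)", level = NA_character_,
                     stringsAsFactors = FALSE)
  for (nm in names(confounds$data)) {
    x <- confounds$data[[nm]]
    if (confounds$types[[nm]] == "numeric") {
      if (var(x) == 0)
        stop_validation("numeric covariate '%s' is constant", nm)
      cols[[nm]] <- as.numeric(x)
      meta <- rbind(meta, data.frame(covariate = nm, level = NA_character_))
    } else {
      lev <- sort(unique(as.character(x)))   # lexicographic; first = reference
      if (length(lev) < 2L)
        stop_validation("categorical covariate '%s' has a single observed level", nm)
      for (l in lev[-1L]) {
        cols[[paste0(nm, ":", l)]] <- as.numeric(x == l)
        meta <- rbind(meta, data.frame(covariate = nm, level = l))
      }
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- confounds$sample_ids
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    bad <- colnames(M)[qr_M$pivot[(qr_M$rank + 1L):ncol(M)]]
    stop_validation("confound design is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", "))
  }
  structure(M, columns = meta, class = c("design_matrix", class(M)))
}

#' Residualize a block against a design matrix
#'
#' Replaces every column of the block by its least-squares residual
#' against the design (intercept included), so that the returned columns
#' are orthogonal to every design column.  The solve uses a rank-revealing
#' QR decomposition rather than explicit normal equations.
#'
#' @param block a [data_block()].
#' @param design a design matrix from [encode_confounds()] (any full-rank
#'   numeric matrix with matching rows is accepted).
#' @return a [data_block()] of residuals with unchanged names.
#' @export
residualize <- function(block, design) {
  if (!inherits(block, "data_block"))
    stop_validation("residualize() expects a data_block")
  design <- unclass(design)
  if (nrow(design) != nrow(block$values))
    stop_validation("design has %d rows but block has %d samples",
                    nrow(design), nrow(block$values))
  qr_D <- qr(design)
  if (qr_D$rank < ncol(design))
    stop_validation("design matrix is rank deficient; encode_confounds() enforces full rank")
  res <- qr.resid(qr_D, block$values)
  data_block(res, block$sample_ids, block$variable_names)
}

#' Standardize a block to zero mean and unit variance
#'
#' Columns are centered and scaled to sample standard deviation one
#' (denominator `n - 1`, consistent with the covariance definitions used
#' by the decompositions).  A zero-variance column is an error.
#'
#' @param block a [data_block()].
#' @return a standardized [data_block()].
#' @export
standardize <- function(block) {
  if (!inherits(block, "data_block"))
    stop_validation("standardize() expects a data_block")
  v <- block$values
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop_validation("zero-variance column(s): %s",
                    paste(block$variable_names[sds == 0], collapse = ", "))
  out <- scale(v, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  data_block(out, block$sample_ids, block$variable_names)
}

#' Variance inflation factors of a block
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing variable
#' `j` on all other variables of the block (with intercept).  Perfectly
#' collinear variables are flagged with `Inf` rather than raising an
#' error; the conventional concern threshold is 10.
#'
#' @param block a [data_block()] with more samples than variables.
#' @return named numeric vector of VIF values.
#' @export
vif <- function(block) {
  if (!inherits(block, "data_block"))
    stop_validation("vif() expects a data_block")
  v <- block$values
  n <- nrow(v)
  p <- ncol(v)
  if (n <= p)
    stop_validation("vif() requires more samples (%d) than variables (%d)", n, p)
  if (p == 1L) return(setNames(1, block$variable_names))
  vc <- scale(v, center = TRUE, scale = FALSE)
  out <- setNames(numeric(p), block$variable_names)
  for (j in seq_len(p)) {
    tss <- sum(vc[, j]^2)
    if (tss == 0) { out[j] <- Inf; next }
    rss <- sum(qr.resid(qr(vc[, -j, drop = FALSE]), vc[, j])^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Preprocess two blocks for cross-decomposition
#'
#' The fixed pipeline applied before any fit: align samples by identifier,
#' regress the encoded covariates out of both blocks, then standardize
#' every column.  The order (residualize, then standardize) is enforced
#' here so that all downstream fits see identically prepared data.
#'
#' @param x,y [data_block()]s (brain and behavior blocks).
#' @param confounds optional [confound_table()]; `NULL` skips covariate
#'   removal.
#' @param skip_residualization bypass covariate removal even when
#'   `confounds` is supplied (sensitivity escape hatch).
#' @return list with standardized blocks `x`, `y` and the `design` matrix
#'   used (`NULL` when no residualization was done).
#' @export
preprocess_blocks <- function(x, y, confounds = NULL,
                              skip_residualization = FALSE) {
  al <- align_samples(x, y, confounds)
  design <- NULL
  if (!is.null(al$confounds) && !skip_residualization) {
    design <- encode_confounds(al$confounds)
    al$x <- residualize(al$x, design)
    al$y <- residualize(al$y, design)
  }
  list(x = standardize(al$x), y = standardize(al$y), design = design)
}
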