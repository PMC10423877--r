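#' Create a data block
#'
#' A data block is the unit of analysis throughout the package: an
#' `n x p` numeric matrix of `n` samples by `p` variables, carrying unique
#' sample identifiers and unique variable names.  All values must be
#' finite; blocks with missing data must be cleaned before construction.
#'
#' @param values numeric matrix (or object coercible to one), samples in
#'   rows, variables in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `values`, or `S1..Sn` when absent.
#' @param variable_names character vector of unique variable names; defaults
#'   to the colnames of `values`, or `V1..Vp` when absent.
#' @return An object of class `data_block` with fields `values`,
#'   `sample_ids` and `variable_names`.
#' @seealso [read_block()], [standardize()], [residualize()]
#' @export
data_block <- function(values, sample_ids = NULL, variable_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("S", seq_len(n)))
  variable_names <- as.character(variable_names %||% colnames(values) %||%
                                   paste0("V", seq_len(p)))
  if (length(sample_ids) != n)
    stop_validation("length of sample_ids (%d) != number of rows (%d)",
                    length(sample_ids), n)
  if (length(variable_names) != p)
    stop_validation("length of variable_names (%d) != number of columns (%d)",
                    length(variable_names), p)
  if (anyDuplicated(sample_ids))
    stop_validation("sample_ids are not unique (first duplicate: '%s')",
                    sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(variable_names))
    stop_validation("variable_names are not unique (first duplicate: '%s')",
                    variable_names[duplicated(variable_names)][1L])
  if (!all(is.finite(values)))
    stop_validation("values contain %d missing or non-finite entries",
                    sum(!is.finite(values)))
  dimnames(values) <- list(sample_ids, variable_names)
  structure(list(values = values, sample_ids = sample_ids,
                 variable_names = variable_names),
            class = "data_block")
}

#' @export
as.matrix.data_block <- function(x, ...) x$values

#' @export
dim.data_block <- function(x) dim(x$values)

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  variables:", paste(utils::head(x$variable_names, 5), collapse = ", "),
      if (ncol(x$values) > 5) "..." else "", "\n")
  invisible(x)
}

#' Read / write a data block as a delimited table
#'
#' The delimiter is chosen from the file extension: `.tsv`/`.txt` are read
#' as tab-separated, anything else as comma-separated.  The identifier
#' column becomes the block's `sample_ids`; remaining columns must be
#' numeric.
#'
#' @param path file path.
#' @param id_col name of the sample-identifier column (default
#'   `"sample_id"`).
#' @return `read_block()` returns a [data_block()]; `write_block()` returns
#'   `path` invisibly.
#' @export
read_block <- function(path, id_col = "sample_id") {
  df <- read_delimited(path)
  if (!id_col %in% names(df))
    stop_validation("column '%s' not found in %s", id_col, path)
  ids <- as.character(df[[id_col]])
  vals <- df[setdiff(names(df), id_col)]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num))
    stop_validation("non-numeric column(s) in %s: %s", path,
                    paste(non_num, collapse = ", "))
  data_block(as.matrix(vals), sample_ids = ids)
}

#' @rdname read_block
#' @param block a [data_block()].
#' @export
write_block <- function(block, path, id_col = "sample_id") {
  df <- data.frame(id = block$sample_ids, block$values,
                   check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  write_delimited(df, path)
  invisible(path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  else
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

write_delimited <- function(df, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Create a confound table
#'
#' Holds the per-sample covariates that are regressed out of both blocks.
#' Numeric columns are kept as numeric covariates; character or factor
#' columns are treated as categorical and must have at least two observed
#' levels.
#'
#' @param df data.frame containing an identifier column plus covariates.
#' @param id_col name of the sample-identifier column.
#' @return An object of class `confound_table` with fields `sample_ids`,
#'   `data` (covariate data.frame) and `types` (named vector,
#'   `"numeric"` or `"categorical"`).
#' @export
confound_table <- function(df, id_col = "sample_id") {
  if (!id_col %in% names(df))
    stop_validation("column '%s' not found in confound table", id_col)
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop_validation("confound sample_ids are not unique")
  dat <- df[setdiff(names(df), id_col)]
  if (!ncol(dat)) stop_validation("confound table has no covariate columns")
  if (any(!complete.cases(dat)))
    stop_validation("confound table contains missing values")
  types <- character(ncol(dat))
  names(types) <- names(dat)
  for (nm in names(dat)) {
    if (is.numeric(dat[[nm]])) {
      if (!all(is.finite(dat[[nm]])))
        stop_validation("non-finite values in numeric covariate '%s'", nm)
      types[nm] <- "numeric"
    } else {
      f <- factor(as.character(dat[[nm]]))
      if (nlevels(f) < 2L)
        stop_validation("categorical covariate '%s' has fewer than 2 observed levels", nm)
      dat[[nm]] <- f
      types[nm] <- "categorical"
    }
  }
  structure(list(sample_ids = ids, data = dat, types = types),
            class = "confound_table")
}

#' @rdname confound_table
#' @param path file path of a delimited covariate table.
#' @export
read_confounds <- function(path, id_col = "sample_id") {
  confound_table(read_delimited(path), id_col = id_col)
}

#' @rdname confound_table
#' @param confounds a `confound_table`.
#' @export
write_confounds <- function(confounds, path, id_col = "sample_id") {
  df <- data.frame(id = confounds$sample_ids, confounds$data,
                   check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  write_delimited(df, path)
  invisible(path)
}

#' Align blocks and confounds on shared sample identifiers
#'
#' Reorders `y` (and `confounds`, when given) to the sample order of `x`.
#' Sample sets must be identical; the driver never assumes that rows of
#' different files arrive in the same order.
#'
#' @param x,y [data_block()]s.
#' @param confounds optional [confound_table()].
#' @return list with elements `x`, `y` and (possibly `NULL`) `confounds`,
#'   all in `x`'s sample order.
#' @export
align_samples <- function(x, y, confounds = NULL) {
  ids <- x$sample_ids
  check_same_ids <- function(other_ids, what) {
    missing <- setdiff(ids, other_ids)
    extra <- setdiff(other_ids, ids)
    if (length(missing) || length(extra))
      stop_validation(
        "sample identifiers of %s do not match the first block (%d missing, %d extra; e.g. %s)",
        what, length(missing), length(extra),
        paste(utils::head(c(missing, extra), 3), collapse = ", "))
  }
  check_same_ids(y$sample_ids, "second block")
  y2 <- data_block(y$values[match(ids, y$sample_ids), , drop = FALSE],
                   sample_ids = ids, variable_names = y$variable_names)
  conf2 <- NULL
  if (!is.null(confounds)) {
    check_same_ids(confounds$sample_ids, "confound table")
    ord <- match(ids, confounds$sample_ids)
    conf2 <- structure(list(sample_ids = ids,
                            data = confounds$data[ord, , drop = FALSE],
                            types = confounds$types),
                       class = "confound_table")
    rownames(conf2$data) <- NULL
  }
  list(x = x, y = y2, confounds = conf2)
}
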