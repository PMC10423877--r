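# JSON / TSV serialization of fits and reports, plus the run-config hash
# embedded in every output for rerun verification.

# 32-bit FNV-1a over the UTF-8 bytes of a string; pure-R modular
# arithmetic (no external hash dependency).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  two32 <- 4294967296
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # h * 16777619 mod 2^32 without exceeding double precision
    h <- ((h %% 65536) * 16777619 + ((h %/% 65536) * 16777619 %% 65536) * 65536) %% two32
  }
  h
}

#' Hash a run configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON serialization; written into
#' every pipeline output so a rerun can be matched to its configuration.
#'
#' @param config any jsonlite-serializable object.
#' @return 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  if (inherits(config, "run_config")) config <- config_as_list(config)
  h <- fnv1a32(as.character(
    jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Serialize a fit to JSON / loadings to TSV
#'
#' `write_fit()` stores method, k, weights, association values, loadings
#' and diagnostics; `read_fit()` restores a `cross_fit` (scores are
#' recomputed lazily from weights when blocks are re-supplied, so the
#' JSON stays small).  `write_loadings_tsv()` writes one TSV per block
#' with variable names as rows and components as columns.
#'
#' @param fit a `cross_fit`.
#' @param path output path.
#' @param config_hash optional hash string to embed.
#' @param seed optional seed to embed.
#' @return the path, invisibly.
#' @export
write_fit <- function(fit, path, config_hash = NULL, seed = NULL) {
  obj <- list(method = fit$method, k = fit$k,
              config_hash = config_hash, seed = seed,
              x_variables = fit$x_variables, y_variables = fit$y_variables,
              U = fit$U, V = fit$V, assoc = as.numeric(fit$assoc),
              x_loadings = fit$x_loadings, y_loadings = fit$y_loadings,
              diagnostics = fit$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(M, rn, cn) {
    M <- as.matrix(M)
    dimnames(M) <- list(rn, cn)
    M
  }
  comp <- paste0("C", seq_len(obj$k))
  structure(list(method = obj$method, k = as.integer(obj$k),
                 U = as_mat(obj$U, obj$x_variables, comp),
                 V = as_mat(obj$V, obj$y_variables, comp),
                 T = NULL, S = NULL,
                 assoc = setNames(obj$assoc, comp),
                 x_variables = obj$x_variables,
                 y_variables = obj$y_variables,
                 x_loadings = as_mat(obj$x_loadings, obj$x_variables, comp),
                 y_loadings = as_mat(obj$y_loadings, obj$y_variables, comp),
                 diagnostics = obj$diagnostics,
                 details = list(), sample_ids = NULL),
            class = "cross_fit")
}

#' @rdname write_fit
#' @param dir directory for the two TSV files (named
#'   `<method>_x_loadings.tsv`, `<method>_y_loadings.tsv`).
#' @export
write_loadings_tsv <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("x", "y")) {
    L <- fit[[paste0(side, "_loadings")]]
    df <- data.frame(variable = rownames(L), L, check.names = FALSE)
    write.table(df,
                file.path(dir, sprintf("%s_%s_loadings.tsv",
                                       tolower(fit$method), side)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Serialize a permutation report
#'
#' JSON carries the full null distribution; the TSV is the per-component
#' summary (component, observed rho, p, explained variance per block).
#'
#' @param report a [permutation_test()] result.
#' @param json_path,tsv_path output paths (`NULL` skips either).
#' @param config_hash optional hash string to embed.
#' @return `report`, invisibly.
#' @export
write_permutation_report <- function(report, json_path = NULL,
                                     tsv_path = NULL, config_hash = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(method = report$method, B = report$B, seed = report$seed,
           config_hash = config_hash, k = report$k,
           observed_rho = as.numeric(report$observed_rho),
           p_values = as.numeric(report$p_values),
           explained_variance = lapply(report$explained_variance, as.numeric),
           null_rho = report$null_rho),
      json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  if (!is.null(tsv_path)) {
    write.table(
      data.frame(component = names(report$observed_rho),
                 observed_rho = as.numeric(report$observed_rho),
                 p_value = as.numeric(report$p_values),
                 explained_variance_x = as.numeric(report$explained_variance$x),
                 explained_variance_y = as.numeric(report$explained_variance$y)),
      tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

#' Serialize a comparison report
#'
#' JSON carries counts, dominant dimensions and all pairwise alignments;
#' the TSV is a long-format table of pairwise matched cosines.
#'
#' @param report a [compare_methods()] result.
#' @param json_path,tsv_path output paths (`NULL` skips either).
#' @param config_hash optional hash string to embed.
#' @return `report`, invisibly.
#' @export
write_comparison_report <- function(report, json_path = NULL,
                                    tsv_path = NULL, config_hash = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(methods = report$methods, alpha = report$alpha,
           config_hash = config_hash,
           n_significant = as.list(report$n_significant),
           significant = report$significant,
           dominant_dimension = report$dominant_dimension,
           p_values = report$p_values,
           observed_rho = report$observed_rho,
           alignments = lapply(report$alignments, function(a)
             as.data.frame(unclass(a)[c("comp_a", "comp_b", "cosine", "sign")]))),
      json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  if (!is.null(tsv_path)) {
    rows <- lapply(names(report$alignments), function(nm) {
      a <- report$alignments[[nm]]
      pair <- strsplit(nm, "_vs_", fixed = TRUE)[[1]]
      data.frame(method_a = pair[1], method_b = pair[2],
                 comp_a = a$comp_a, comp_b = a$comp_b,
                 cosine = a$cosine, sign = a$sign)
    })
    write.table(do.call(rbind, rows), tsv_path, sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
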