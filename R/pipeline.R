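# End-to-end driver: simulate/load -> residualize -> standardize ->
# fit (per method) -> permutation test -> cross-method comparison.

#' Build and validate a run configuration
#'
#' Exactly one input source must be given: either the three file paths
#' (`x_file`, `y_file`, optionally `confound_file`) or a synthetic source
#' (`synthetic_n`, or a full [synthetic_spec()] via `spec`).
#'
#' @param x_file,y_file,confound_file delimited input tables (CSV/TSV by
#'   extension) with a shared `sample_id` column.
#' @param synthetic_n sample size for the default ABCD-like generator.
#' @param spec a [synthetic_spec()] overriding `synthetic_n`.
#' @param methods character vector among `"CCA"`, `"PLSC"`, `"PLSR"`.
#' @param k number of components (default 4, capped at `min(p, m)` at fit
#'   time).
#' @param B permutation count (default 1000).
#' @param alpha significance level in `(0, 1]`.
#' @param seed integer master seed (generator and permutation streams are
#'   derived from it).
#' @param out_dir output directory.
#' @param include_icv synthetic runs: add the intracranial-volume
#'   covariate.
#' @param skip_residualization bypass covariate removal.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(x_file = NULL, y_file = NULL, confound_file = NULL,
                       synthetic_n = NULL, spec = NULL,
                       methods = c("CCA", "PLSC", "PLSR"),
                       k = 4L, B = 1000L, alpha = 0.05, seed = 1L,
                       out_dir = "crossdecomp_run",
                       include_icv = FALSE, skip_residualization = FALSE) {
  from_files <- !is.null(x_file) || !is.null(y_file)
  from_synth <- !is.null(synthetic_n) || !is.null(spec)
  if (from_files == from_synth)
    stop_validation("exactly one input source required: x_file/y_file XOR synthetic_n/spec")
  if (from_files && (is.null(x_file) || is.null(y_file)))
    stop_validation("both x_file and y_file are required for file input")
  methods <- toupper(methods)
  bad <- setdiff(methods, c("CCA", "PLSC", "PLSR"))
  if (length(bad) || !length(methods))
    stop_validation("unknown method(s): %s", paste(bad, collapse = ", "))
  if (k < 1L) stop_validation("k must be >= 1")
  if (B < 1L) stop_validation("B must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop_validation("alpha must lie in (0, 1]")
  structure(list(x_file = x_file, y_file = y_file,
                 confound_file = confound_file,
                 synthetic_n = synthetic_n, spec = spec,
                 methods = methods, k = as.integer(k), B = as.integer(B),
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 include_icv = isTRUE(include_icv),
                 skip_residualization = isTRUE(skip_residualization)),
            class = "run_config")
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL        # hash identifies the analysis, not its location
  if (!is.null(cfg$spec)) {
    cfg$spec <- list(n_samples = cfg$spec$n_samples, seed = cfg$spec$seed,
                     n_brain = cfg$spec$n_brain, n_psych = cfg$spec$n_psych,
                     strengths = vapply(cfg$spec$components, `[[`,
                                        numeric(1), "strength"))
  }
  cfg
}

log_stage <- function(stage, fmt = "", ...) {
  msg <- if (nzchar(fmt)) sprintf(fmt, ...) else ""
  message(sprintf("[crossdecomp] %s %s", stage, msg))
}

#' Run the full comparison pipeline
#'
#' Executes every stage on one configuration and writes all artifacts to
#' `config$out_dir`: the (possibly simulated) input tables, VIF
#' diagnostics, one fit JSON and loadings TSV pair per method, one
#' permutation report per method, and the cross-method comparison report.
#' Every JSON embeds the configuration hash and seed so reruns are
#' verifiable; identical configurations produce byte-identical outputs.
#' Stage failures propagate with the stage name prepended.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `comparison`, `fits`, `reports`,
#'   `preprocessed`, `config_hash` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_validation("run_pipeline() expects a run_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config_as_list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = unique(c(class(e)[1], "cd_error", "error"))))
    })
  }

  log_stage("input", "config hash %s, seed %d", hash, config$seed)
  dat <- stage("input", {
    if (!is.null(config$spec) || !is.null(config$synthetic_n)) {
      spec <- config$spec %||%
        default_abcd_like_spec(config$synthetic_n, seed = config$seed,
                               include_icv = config$include_icv)
      ds <- generate_dataset(spec)
      write_dataset(ds, file.path(out, "data"))
      log_stage("input", "simulated n=%d, p=%d, m=%d (seed %d)",
                nrow(ds$brain$values), ncol(ds$brain$values),
                ncol(ds$psych$values), spec$seed)
      ds
    } else {
      list(brain = read_block(config$x_file),
           psych = read_block(config$y_file),
           confounds = if (!is.null(config$confound_file))
             read_confounds(config$confound_file),
           truth = NULL)
    }
  })

  pre <- stage("preprocess", preprocess_blocks(
    dat$brain, dat$psych, dat$confounds,
    skip_residualization = config$skip_residualization))
  log_stage("preprocess", "residualized=%s",
            !is.null(pre$design))

  stage("diagnostics", {
    # VIF needs n > p; for under-determined blocks record NA rather than
    # aborting the run
    safe_vif <- function(b) {
      if (nrow(b$values) > ncol(b$values)) vif(b)
      else setNames(rep(NA_real_, ncol(b$values)), b$variable_names)
    }
    v <- c(safe_vif(pre$x), safe_vif(pre$y))
    write.table(data.frame(variable = names(v), vif = as.numeric(v)),
                file.path(out, "vif.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  })

  k <- min(config$k, ncol(pre$x$values), ncol(pre$y$values))
  fits <- list()
  reports <- list()
  for (i in seq_along(config$methods)) {
    method <- config$methods[i]
    fits[[method]] <- stage(paste0("fit:", method),
                            fit_method(pre$x, pre$y, method, k = k))
    log_stage(paste0("fit:", method), "assoc %s",
              paste(format(round(fits[[method]]$assoc, 4)), collapse = " "))
    write_fit(fits[[method]],
              file.path(out, sprintf("fit_%s.json", tolower(method))),
              config_hash = hash, seed = config$seed)
    write_loadings_tsv(fits[[method]], out)
    # distinct derived permutation stream per method, reproducible from
    # the master seed
    reports[[method]] <- stage(
      paste0("permtest:", method),
      permutation_test(pre$x, pre$y, method, k = k, B = config$B,
                       seed = config$seed + 1000L * i))
    log_stage(paste0("permtest:", method), "p = %s",
              paste(signif(reports[[method]]$p_values, 3), collapse = " "))
    write_permutation_report(
      reports[[method]],
      json_path = file.path(out, sprintf("perm_%s.json", tolower(method))),
      tsv_path = file.path(out, sprintf("perm_%s.tsv", tolower(method))),
      config_hash = hash)
  }

  comparison <- stage("compare",
                      compare_methods(fits, reports, alpha = config$alpha))
  write_comparison_report(comparison,
                          json_path = file.path(out, "comparison.json"),
                          tsv_path = file.path(out, "comparison_cosines.tsv"),
                          config_hash = hash)
  log_stage("compare", "significant components: %s",
            paste(sprintf("%s=%d", names(comparison$n_significant),
                          comparison$n_significant), collapse = " "))
  invisible(list(comparison = comparison, fits = fits, reports = reports,
                 preprocessed = pre, truth = dat$truth,
                 config_hash = hash, out_dir = out))
}
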