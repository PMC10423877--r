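#' Region and dimension names for the ABCD-like synthetic dataset
#'
#' Builds variable names for a synthetic brain block: left/right cortical
#' regions from the 34-region Desikan-Killiany surface parcellation,
#' followed by subcortical segmentation structures.  For the default
#' 68 + 19 layout these match the region sets commonly extracted from
#' FreeSurfer; for other sizes generic names are produced.
#'
#' @param n_cortical,n_subcortical region counts (defaults 68 and 19).
#' @return character vector of length `n_cortical + n_subcortical`.
#' @export
brain_region_names <- function(n_cortical = 68L, n_subcortical = 19L) {
  dk <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
          "cuneus", "entorhinal", "frontalpole", "fusiform",
          "inferiorparietal", "inferiortemporal", "insula",
          "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
          "lingual", "medialorbitofrontal", "middletemporal",
          "paracentral", "parahippocampal", "parsopercularis",
          "parsorbitalis", "parstriangularis", "pericalcarine",
          "postcentral", "posteriorcingulate", "precentral", "precuneus",
          "rostralanteriorcingulate", "rostralmiddlefrontal",
          "superiorfrontal", "superiorparietal", "superiortemporal",
          "supramarginal", "temporalpole", "transversetemporal")
  sub <- c("Left-Thalamus", "Right-Thalamus", "Left-Caudate",
           "Right-Caudate", "Left-Putamen", "Right-Putamen",
           "Left-Pallidum", "Right-Pallidum", "Left-Hippocampus",
           "Right-Hippocampus", "Left-Amygdala", "Right-Amygdala",
           "Left-Accumbens", "Right-Accumbens", "Left-VentralDC",
           "Right-VentralDC", "Left-Cerebellum-Cortex",
           "Right-Cerebellum-Cortex", "Brain-Stem")
  cort <- if (n_cortical == 68L)
    c(paste0("lh_", dk), paste0("rh_", dk))
  else paste0("ctx", seq_len(n_cortical))
  subc <- if (n_subcortical == 19L) sub else paste0("subctx", seq_len(n_subcortical))
  c(cort, subc)
}

psych_dimension_names <- function(n_psych) {
  if (n_psych == 4L) c("general", "adhd", "conduct", "internalizing")
  else paste0("factor", seq_len(n_psych))
}

#' Planted cross-block component
#'
#' A rank-1 association planted by the generator: a unit-norm brain
#' pattern, a unit-norm psychopathology pattern, and a `strength` equal to
#' the population Pearson correlation of the latent score pair
#' `(X u, Y v)` induced by the component.  Patterns are normalized to unit
#' Euclidean norm on construction.
#'
#' @param brain_pattern numeric vector over brain variables.
#' @param psych_pattern numeric vector over psychopathology variables.
#' @param strength population latent-pair correlation, in `[0, 1)`.
#' @return object of class `planted_component`.
#' @export
planted_component <- function(brain_pattern, psych_pattern, strength) {
  nb <- sqrt(sum(brain_pattern^2))
  np <- sqrt(sum(psych_pattern^2))
  if (!is.finite(nb) || nb == 0 || !is.finite(np) || np == 0)
    stop_validation("planted pattern vectors must be finite and non-zero")
  if (!is.finite(strength) || strength < 0 || strength >= 1)
    stop_validation("component strength must be finite, >= 0 and < 1 (got %s)",
                    format(strength))
  structure(list(brain_pattern = brain_pattern / nb,
                 psych_pattern = psych_pattern / np,
                 strength = strength),
            class = "planted_component")
}

#' Confound model for the synthetic generator
#'
#' Describes how covariates are drawn and how they contaminate the two
#' blocks.  Each numeric covariate has a sampling mean/sd and a slope per
#' block (scalar, applied to every variable, or a vector with one entry
#' per variable).  Each categorical covariate has sampling probabilities
#' and an additive offset per level per block.  An optional intracranial
#' volume (`icv`) term is a numeric covariate acting on the brain block
#' only, used for sensitivity analyses.
#'
#' @param numeric named list; each element a list with `mean`, `sd` and
#'   `slope` (named list/vector with elements `brain` and `psych`).
#' @param categorical named list; each element a list with `levels`,
#'   `probs`, and `offsets` (list with `brain` and `psych`, each a vector
#'   named by level, scalar per level).
#' @param icv `NULL` or a list with `mean`, `sd`, `slope` (scalar slope on
#'   every brain variable).
#' @return object of class `confound_model`.
#' @export
confound_model <- function(numeric = list(), categorical = list(), icv = NULL) {
  for (nm in names(categorical)) {
    cv <- categorical[[nm]]
    if (length(cv$levels) < 2L)
      stop_validation("categorical covariate '%s' must have >= 2 levels", nm)
    if (length(cv$probs) != length(cv$levels) || abs(sum(cv$probs) - 1) > 1e-8)
      stop_validation("probs of categorical covariate '%s' must match its levels and sum to 1", nm)
    for (blk in c("brain", "psych")) {
      off <- cv$offsets[[blk]]
      if (!all(cv$levels %in% names(off)))
        stop_validation("offsets$%s of categorical covariate '%s' must be named for every level",
                        blk, nm)
    }
  }
  for (nm in names(numeric)) {
    nv <- numeric[[nm]]
    if (!all(c("mean", "sd", "slope") %in% names(nv)) || nv$sd <= 0)
      stop_validation("numeric covariate '%s' needs mean, sd > 0 and slope", nm)
  }
  if (!is.null(icv) && (!is.numeric(icv$slope) || icv$sd <= 0))
    stop_validation("icv needs mean, sd > 0 and a numeric slope")
  structure(list(numeric = numeric, categorical = categorical, icv = icv),
            class = "confound_model")
}

#' Default covariate model mimicking the ABCD demographic structure
#'
#' Age in months (mean 118.92, sd 7.41), sex F/M at 47.8/52.2%,
#' race-ethnicity at 51.3/21.4/14.8/12.5% and a three-level MRI
#' manufacturer at 60/25/15%.  Slopes and offsets are modest relative to
#' the unit residual noise of the generator.  `include_icv = TRUE` adds an
#' intracranial-volume covariate (cm^3) affecting brain variables only.
#'
#' @param include_icv add the ICV sensitivity covariate?
#' @return a [confound_model()].
#' @export
default_confound_model <- function(include_icv = FALSE) {
  cm <- confound_model(
    numeric = list(
      age = list(mean = 118.92, sd = 7.41,
                 slope = list(brain = -0.01, psych = 0.005))),
    categorical = list(
      sex = list(
        levels = c("F", "M"), probs = c(0.4782, 0.5218),
        offsets = list(brain = c(F = 0, M = 0.6),
                       psych = c(F = 0, M = 0.2))),
      race_ethnicity = list(
        levels = c("NH-White", "Hispanic", "Black", "Other"),
        probs = c(0.5126, 0.2140, 0.1480, 0.1254),
        offsets = list(
          brain = c("NH-White" = 0, "Hispanic" = -0.1, "Black" = -0.15,
                    "Other" = -0.05),
          psych = c("NH-White" = 0, "Hispanic" = 0.05, "Black" = 0.1,
                    "Other" = 0.05))),
      manufacturer = list(
        levels = c("SIEMENS", "GE", "Philips"),
        probs = c(0.60, 0.25, 0.15),
        offsets = list(brain = c(SIEMENS = 0, GE = 0.25, Philips = -0.2),
                       psych = c(SIEMENS = 0, GE = 0, Philips = 0)))),
    icv = if (include_icv) list(mean = 1450, sd = 130, slope = 0.003) else NULL)
  cm
}

#' Specification of a synthetic two-block dataset
#'
#' @param n_samples number of samples.
#' @param components list of [planted_component()]s with strictly
#'   decreasing strengths.
#' @param confound_model a [confound_model()] or `NULL` for no covariate
#'   effects.
#' @param n_brain,n_cortical,n_subcortical brain-variable counts; must
#'   satisfy `n_cortical + n_subcortical == n_brain` (defaults 87 = 68 + 19).
#' @param n_psych number of psychopathology dimensions (default 4).
#' @param noise_sd length-2 named vector `c(brain = , psych = )` of
#'   positive residual standard deviations.
#' @param seed integer RNG seed; a single stream drives covariates,
#'   latents and noise.
#' @param brain_names,psych_names optional variable names.
#' @return object of class `synthetic_spec`.
#' @seealso [default_abcd_like_spec()], [generate_dataset()]
#' @export
synthetic_spec <- function(n_samples, components = list(),
                           confound_model = NULL,
                           n_brain = 87L, n_cortical = 68L,
                           n_subcortical = 19L, n_psych = 4L,
                           noise_sd = c(brain = 1, psych = 1), seed = 1L,
                           brain_names = NULL, psych_names = NULL) {
  spec <- structure(
    list(n_samples = as.integer(n_samples), components = components,
         confound_model = confound_model, n_brain = as.integer(n_brain),
         n_cortical = as.integer(n_cortical),
         n_subcortical = as.integer(n_subcortical),
         n_psych = as.integer(n_psych), noise_sd = noise_sd,
         seed = as.integer(seed),
         brain_names = brain_names %||%
           brain_region_names(n_cortical, n_subcortical),
         psych_names = psych_names %||% psych_dimension_names(n_psych)),
    class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_samples < 1L) stop_validation("n_samples must be >= 1")
    if (n_cortical + n_subcortical != n_brain)
      stop_validation("n_cortical + n_subcortical (%d) != n_brain (%d)",
                      n_cortical + n_subcortical, n_brain)
    if (length(brain_names) != n_brain || length(psych_names) != n_psych)
      stop_validation("variable name lengths do not match n_brain / n_psych")
    if (!all(c("brain", "psych") %in% names(noise_sd)) ||
        any(!is.finite(noise_sd[c("brain", "psych")])) ||
        any(noise_sd[c("brain", "psych")] <= 0))
      stop_validation("noise_sd must hold positive finite 'brain' and 'psych' entries")
    strengths <- numeric(0)
    for (i in seq_along(components)) {
      cp <- components[[i]]
      if (!inherits(cp, "planted_component"))
        stop_validation("components[[%d]] is not a planted_component", i)
      if (length(cp$brain_pattern) != n_brain)
        stop_validation("components[[%d]]: brain pattern length %d != n_brain %d",
                        i, length(cp$brain_pattern), n_brain)
      if (length(cp$psych_pattern) != n_psych)
        stop_validation("components[[%d]]: psych pattern length %d != n_psych %d",
                        i, length(cp$psych_pattern), n_psych)
      if (!is.finite(cp$strength) || cp$strength < 0)
        stop_validation("components[[%d]]: strength must be finite and non-negative", i)
      strengths <- c(strengths, cp$strength)
    }
    if (length(strengths) > 1 && any(diff(strengths) >= 0))
      stop_validation("component strengths must be strictly decreasing")
  })
  invisible(spec)
}

#' Default ABCD-like synthetic specification
#'
#' Encodes the qualitative structure reported for the real analysis as the
#' generator's ground truth: a leading component coupling an all-negative,
#' near-global brain pattern with a psychopathology pattern dominated by
#' the general factor (strength 0.16), plus a weaker second component
#' (strength 0.11) localized on six regions implicated across methods
#' (bilateral caudal middle frontal, inferior parietal, superior temporal)
#' and driven by the ADHD-specific factor.  Covariates follow
#' [default_confound_model()]; residual noise is unit sd in both blocks.
#'
#' @param n_samples number of samples (>= 50).
#' @param seed integer RNG seed.
#' @param include_icv add the intracranial-volume covariate?
#' @param confounds set `FALSE` for a covariate-free variant.
#' @return a [synthetic_spec()].
#' @export
default_abcd_like_spec <- function(n_samples, seed = 1L,
                                   include_icv = FALSE, confounds = TRUE) {
  if (n_samples < 50L)
    stop_validation("n_samples must be >= 50 for the default spec (got %d)",
                    n_samples)
  nb <- 87L
  names <- brain_region_names()
  # global negative pattern with smooth amplitude variation (not exactly
  # uniform, so recovery is a real test of direction, not just of sign)
  u1 <- -(1 + 0.25 * cos(2 * pi * (seq_len(nb) - 1) / nb))
  v1 <- c(general = 1, adhd = 0.12, conduct = 0.12, internalizing = 0.06)
  focal <- c("caudalmiddlefrontal", "inferiorparietal", "superiortemporal")
  u2 <- numeric(nb)
  u2[names %in% c(paste0("lh_", focal), paste0("rh_", focal))] <- 1
  v2 <- c(general = 0, adhd = 1, conduct = 0, internalizing = 0.15)
  synthetic_spec(
    n_samples = n_samples,
    components = list(planted_component(u1, v1, 0.16),
                      planted_component(u2, v2, 0.11)),
    confound_model = if (confounds) default_confound_model(include_icv),
    seed = seed)
}

# slope/offset vectors recycled to one entry per variable
as_effect_vector <- function(x, p) {
  x <- as.numeric(x)
  if (length(x) == 1L) rep(x, p)
  else if (length(x) == p) x
  else stop_validation("effect vector has length %d; expected 1 or %d",
                       length(x), p)
}

#' Generate a synthetic two-block dataset
#'
#' Draws covariates, `k` shared standard-normal latent scores (one per
#' planted component) and i.i.d. Gaussian noise, and assembles
#' `block = covariate effects + sum_c scale_c * latent_c * pattern_c' + noise`.
#' The signal scale of component `c` is calibrated as
#' `scale = noise_sd * sqrt(strength / (1 - strength))` in each block, so
#' that the population correlation of the latent score pair
#' `(X u_c, Y v_c)` equals `strength` (exactly so when patterns are
#' orthogonal across components).
#'
#' All randomness comes from one RNG stream seeded with `spec$seed`:
#' identical specs produce bit-identical datasets.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `brain` ([data_block()], `n x n_brain`),
#'   `psych` (`n x n_psych`), `confounds` ([confound_table()] or `NULL`)
#'   and `truth` (class `synthetic_truth`: planted components, signal
#'   scales, realized latent scores, confound coefficient tables, seed).
#' @export
generate_dataset <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_brain
  m <- spec$n_psych
  k <- length(spec$components)

  brain <- matrix(0, n, p)
  psych <- matrix(0, n, m)
  conf <- NULL
  coef_brain <- list()
  coef_psych <- list()

  cm <- spec$confound_model
  if (!is.null(cm)) {
    cov_df <- list()
    for (nm in names(cm$numeric)) {
      nv <- cm$numeric[[nm]]
      x <- rnorm(n, nv$mean, nv$sd)
      cov_df[[nm]] <- x
      sb <- as_effect_vector(nv$slope$brain %||% nv$slope["brain"], p)
      sp <- as_effect_vector(nv$slope$psych %||% nv$slope["psych"], m)
      brain <- brain + outer(x, sb)
      psych <- psych + outer(x, sp)
      coef_brain[[nm]] <- sb
      coef_psych[[nm]] <- sp
    }
    for (nm in names(cm$categorical)) {
      cv <- cm$categorical[[nm]]
      lev <- sample(cv$levels, n, replace = TRUE, prob = cv$probs)
      cov_df[[nm]] <- lev
      idx <- match(lev, cv$levels)
      offb <- do.call(rbind, lapply(cv$levels,
        function(l) as_effect_vector(cv$offsets$brain[[l]], p)))
      offp <- do.call(rbind, lapply(cv$levels,
        function(l) as_effect_vector(cv$offsets$psych[[l]], m)))
      brain <- brain + offb[idx, , drop = FALSE]
      psych <- psych + offp[idx, , drop = FALSE]
      coef_brain[[nm]] <- structure(offb, dimnames = list(cv$levels, NULL))
      coef_psych[[nm]] <- structure(offp, dimnames = list(cv$levels, NULL))
    }
    if (!is.null(cm$icv)) {
      x <- rnorm(n, cm$icv$mean, cm$icv$sd)
      cov_df[["icv"]] <- x
      sb <- as_effect_vector(cm$icv$slope, p)
      brain <- brain + outer(x, sb)
      coef_brain[["icv"]] <- sb
    }
    conf <- confound_table(
      data.frame(sample_id = paste0("S", seq_len(n)), cov_df,
                 check.names = FALSE, stringsAsFactors = FALSE))
  }

  Z <- matrix(rnorm(n * k), n, k)
  scale_b <- scale_p <- numeric(k)
  for (c in seq_len(k)) {
    comp <- spec$components[[c]]
    g <- sqrt(comp$strength / (1 - comp$strength))
    scale_b[c] <- spec$noise_sd[["brain"]] * g
    scale_p[c] <- spec$noise_sd[["psych"]] * g
    brain <- brain + scale_b[c] * outer(Z[, c], comp$brain_pattern)
    psych <- psych + scale_p[c] * outer(Z[, c], comp$psych_pattern)
  }
  brain <- brain + spec$noise_sd[["brain"]] * matrix(rnorm(n * p), n, p)
  psych <- psych + spec$noise_sd[["psych"]] * matrix(rnorm(n * m), n, m)

  ids <- paste0("S", seq_len(n))
  truth <- structure(
    list(components = spec$components, scale_brain = scale_b,
         scale_psych = scale_p, latent = Z,
         confound_coefficients = list(brain = coef_brain, psych = coef_psych),
         noise_sd = spec$noise_sd, seed = spec$seed),
    class = "synthetic_truth")
  list(brain = data_block(brain, ids, spec$brain_names),
       psych = data_block(psych, ids, spec$psych_names),
       confounds = conf, truth = truth)
}

#' Write a generated dataset to a directory
#'
#' Writes `brain.csv`, `psych.csv`, `confounds.csv` (when present) and
#' `truth.json` (planted patterns, strengths, scales, seed; latent scores
#' are omitted to keep the file small).
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_block(dataset$brain, file.path(dir, "brain.csv"))
  write_block(dataset$psych, file.path(dir, "psych.csv"))
  if (!is.null(dataset$confounds))
    write_confounds(dataset$confounds, file.path(dir, "confounds.csv"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(seed = tr$seed, noise_sd = as.list(tr$noise_sd),
         scale_brain = tr$scale_brain, scale_psych = tr$scale_psych,
         components = lapply(tr$components, function(cp)
           list(strength = cp$strength,
                brain_pattern = cp$brain_pattern,
                psych_pattern = cp$psych_pattern))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
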