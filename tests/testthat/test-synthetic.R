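test_that("generator produces the documented shapes and reproduces bit-identically", {
  spec <- default_abcd_like_spec(120, seed = 9)
  d <- generate_dataset(spec)
  expect_identical(dim(d$brain), c(120L, 87L))
  expect_identical(dim(d$psych), c(120L, 4L))
  expect_identical(d$brain$sample_ids, d$psych$sample_ids)
  expect_identical(d$confounds$sample_ids, d$brain$sample_ids)
  expect_identical(colnames(d$psych$values),
                   c("general", "adhd", "conduct", "internalizing"))

  d2 <- generate_dataset(default_abcd_like_spec(120, seed = 9))
  expect_identical(d$brain$values, d2$brain$values)
  expect_identical(d$psych$values, d2$psych$values)
  expect_identical(d$confounds$data, d2$confounds$data)

  d3 <- generate_dataset(default_abcd_like_spec(120, seed = 10))
  expect_false(identical(d$brain$values, d3$brain$values))
})

test_that("spec validation names the violated invariant", {
  expect_error(default_abcd_like_spec(10), regexp = "n_samples",
               class = "cd_validation_error")
  expect_error(synthetic_spec(100, n_brain = 87, n_cortical = 60,
                              n_subcortical = 19),
               regexp = "n_cortical", class = "cd_validation_error")
  comp_short <- planted_component(rep(1, 5), c(1, 0, 0, 0), 0.3)
  expect_error(synthetic_spec(100, components = list(comp_short)),
               regexp = "brain pattern length", class = "cd_validation_error")
  c1 <- planted_component(rep(1, 87), c(1, 0, 0, 0), 0.1)
  c2 <- planted_component(rep(1, 87), c(0, 1, 0, 0), 0.2)
  expect_error(synthetic_spec(100, components = list(c1, c2)),
               regexp = "strictly decreasing", class = "cd_validation_error")
  expect_error(planted_component(rep(1, 87), c(1, 0, 0, 0), 1),
               regexp = "strength", class = "cd_validation_error")
  expect_error(synthetic_spec(100, noise_sd = c(brain = 0, psych = 1)),
               regexp = "noise_sd", class = "cd_validation_error")
})

test_that("zero planted components give independent blocks", {
  spec <- synthetic_spec(2000, components = list(), seed = 31)
  d <- generate_dataset(spec)
  expect_length(d$truth$components, 0)
  expect_null(d$confounds)
  # 87 x 4 null correlations: all should stay at noise level
  expect_lt(max(abs(cor(d$brain$values, d$psych$values))), 0.1)
})

test_that("strength calibrates the population latent-pair correlation", {
  set.seed(77)
  u <- rnorm(87); v <- c(1, 0.3, 0.2, 0.1)
  spec <- synthetic_spec(5000,
                         components = list(planted_component(u, v, 0.3)),
                         seed = 13)
  d <- generate_dataset(spec)
  t_true <- d$brain$values %*% d$truth$components[[1]]$brain_pattern
  s_true <- d$psych$values %*% d$truth$components[[1]]$psych_pattern
  expect_lt(abs(cor(t_true, s_true) - 0.3), 0.05)
})

test_that("psych factors are near-orthogonal at n = 10000 without confounds", {
  spec <- default_abcd_like_spec(10000, seed = 5, confounds = FALSE)
  d <- generate_dataset(spec)
  C <- cor(d$psych$values)
  diag(C) <- 0
  expect_lt(max(abs(C)), 0.05)
})

test_that("default spec has strictly decreasing strengths and the stated scale", {
  spec <- default_abcd_like_spec(9027, seed = 1)
  expect_identical(spec$n_samples, 9027L)
  expect_identical(spec$n_brain, 87L)
  strengths <- vapply(spec$components, `[[`, numeric(1), "strength")
  expect_true(all(diff(strengths) < 0))
  expect_equal(strengths, c(0.16, 0.11))
  # patterns are unit norm; leading brain pattern is globally negative
  for (cp in spec$components) {
    expect_equal(sum(cp$brain_pattern^2), 1, tolerance = 1e-12)
    expect_equal(sum(cp$psych_pattern^2), 1, tolerance = 1e-12)
  }
  expect_true(all(spec$components[[1]]$brain_pattern < 0))
  expect_identical(
    unname(which.max(abs(spec$components[[1]]$psych_pattern))), 1L)  # general factor
})

test_that("planted confound effects are recovered by regression within 3 SE", {
  spec <- default_abcd_like_spec(3000, seed = 17)
  d <- generate_dataset(spec)
  D <- encode_confounds(d$confounds)
  cm <- spec$confound_model
  for (j in c(1, 40, 87)) {
    fitlm <- lm(d$brain$values[, j] ~ D[, -1])
    est <- coef(summary(fitlm))
    # age slope
    i_age <- grep("age", rownames(est))
    expect_lt(abs(est[i_age, "Estimate"] - cm$numeric$age$slope$brain),
              3 * est[i_age, "Std. Error"])
    # sex offset (M vs reference F)
    i_sex <- grep("sex:M", rownames(est))
    expect_lt(abs(est[i_sex, "Estimate"] - cm$categorical$sex$offsets$brain[["M"]]),
              3 * est[i_sex, "Std. Error"])
  }
})

test_that("planted leading component is recovered above the detectability threshold", {
  # At the default strengths the rank-1 cross-correlation signal
  # (r/(1-r) ~= 0.19) only clears the 87x4 sampling-noise level
  # ((sqrt(87)+2)/sqrt(n)) comfortably for n >> 9000; n = 20000 gives a
  # clean green recovery check of the generator + fit chain.
  spec <- default_abcd_like_spec(20000, seed = 11, confounds = FALSE)
  d <- generate_dataset(spec)
  pre <- preprocess_blocks(d$brain, d$psych)
  u1 <- d$truth$components[[1]]$brain_pattern
  for (method in c("CCA", "PLSC", "PLSR")) {
    f <- fit_method(pre$x, pre$y, method, k = 2)
    expect_gt(abs_cos(f$x_loadings[, 1], u1), 0.9)
    expect_identical(
      f$y_variables[which.max(abs(f$y_loadings[, 1]))], "general")
  }
})

test_that("write_dataset writes the four artifacts", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(default_abcd_like_spec(60, seed = 2))
  write_dataset(d, dir)
  expect_true(all(file.exists(file.path(
    dir, c("brain.csv", "psych.csv", "confounds.csv", "truth.json")))))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$components$strength, c(0.16, 0.11))
  b <- read_block(file.path(dir, "brain.csv"))
  expect_equal(b$values, d$brain$values, tolerance = 1e-12)
})
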