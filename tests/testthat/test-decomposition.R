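test_that("CCA attains perfect correlations on an exact linear relationship", {
  set.seed(1)
  X <- rand_block(50, 3, seed = 1)
  M <- matrix(c(2, 0, 1, -1, 1, 0, 0.5, 0, 3), 3, 3)   # invertible
  Y <- data_block(X$values %*% M, X$sample_ids, paste0("Y", 1:3))
  f <- fit_cca(X, Y, k = 3)
  expect_equal(unname(f$assoc), rep(1, 3), tolerance = 1e-8)
})

test_that("CCA is invariant to invertible within-block re-mixing; PLS is not", {
  tb <- toy_blocks(40, 3, 2, seed = 5)
  set.seed(6)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  B <- matrix(rnorm(4), 2, 2) + diag(2)
  Xt <- data_block(tb$X$values %*% A, tb$X$sample_ids, tb$X$variable_names)
  Yt <- data_block(tb$Y$values %*% B, tb$Y$sample_ids, tb$Y$variable_names)

  expect_equal(unname(fit_cca(Xt, Yt, k = 2)$assoc),
               unname(fit_cca(tb$X, tb$Y, k = 2)$assoc), tolerance = 1e-8)

  # rescaling one column must change PLSC/PLSR association values
  Xs <- data_block(sweep(tb$X$values, 2, c(5, 1, 1), `*`),
                   tb$X$sample_ids, tb$X$variable_names)
  expect_gt(abs(fit_plsc(Xs, tb$Y, k = 1)$assoc[1] -
                  fit_plsc(tb$X, tb$Y, k = 1)$assoc[1]), 1e-6)
  expect_gt(abs(fit_plsr(Xs, tb$Y, k = 1)$assoc[1] -
                  fit_plsr(tb$X, tb$Y, k = 1)$assoc[1]), 1e-6)
})

test_that("CCA matches the generalized-eigenproblem oracle", {
  X <- rand_block(30, 3, seed = 7)
  Y <- rand_block(30, 2, seed = 8, prefix = "Y")
  f <- fit_cca(X, Y, k = 2)
  expect_equal(unname(f$assoc), oracle_cca_correlations(X$values, Y$values),
               tolerance = 1e-8)
})

test_that("CCA canonical variates are orthonormal within blocks", {
  tb <- toy_blocks(60, 4, 3, seed = 9)
  f <- fit_cca(tb$X, tb$Y, k = 3)
  expect_equal(cor(f$T), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cor(f$S), diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  # assoc sorted descending within [0, 1]
  expect_true(all(diff(f$assoc) <= 1e-12))
  expect_true(all(f$assoc >= 0 & f$assoc <= 1))
})

test_that("CCA errors on singular covariance and recommends the ridge", {
  X <- rand_block(10, 3, seed = 10)
  Xdup <- data_block(cbind(X$values, X$values[, 1]),
                     X$sample_ids, c(X$variable_names, "dup"))
  Y <- rand_block(10, 2, seed = 11, prefix = "Y")
  expect_error(fit_cca(Xdup, Y, k = 1), regexp = "ridge",
               class = "cd_numerical_error")
  f <- fit_cca(Xdup, Y, k = 1, ridge = "auto")
  expect_true(is.finite(f$assoc[1]))
})

test_that("PLSC handles the scalar case and matches brute-force maximization", {
  # p = m = 1: assoc is |cov|, weights +-1
  x <- rand_block(25, 1, seed = 12)
  y <- data_block(cbind(0.5 * x$values[, 1] + rnorm(25)),
                  x$sample_ids, "y1")
  f1 <- fit_plsc(x, y, k = 1)
  expect_equal(unname(f1$assoc[1]), abs(cov(x$values[, 1], y$values[, 1])),
               tolerance = 1e-12)
  expect_equal(abs(unname(f1$U[, 1])), 1, tolerance = 1e-12)

  # sampled unit vector pairs never beat the SVD optimum; alternating
  # refinement from the best sample converges to it
  tb <- toy_blocks(20, 3, 2, seed = 13)
  f <- fit_plsc(tb$X, tb$Y, k = 2)
  Xc <- scale(tb$X$values, scale = FALSE)
  Yc <- scale(tb$Y$values, scale = FALSE)
  Sxy <- crossprod(Xc, Yc) / 19
  set.seed(14)
  best <- -Inf; best_v <- NULL
  for (i in 1:10000) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(2); v <- v / sqrt(sum(v^2))
    val <- abs(drop(t(u) %*% Sxy %*% v))
    if (val > best) { best <- val; best_v <- v }
  }
  expect_lte(best, f$assoc[1] + 1e-12)
  v <- best_v
  for (i in 1:200) {                      # alternating maximization
    u <- drop(Sxy %*% v); u <- u / sqrt(sum(u^2))
    v <- drop(t(Sxy) %*% u); v <- v / sqrt(sum(v^2))
  }
  expect_equal(drop(t(u) %*% Sxy %*% v), unname(f$assoc[1]),
               tolerance = 1e-8)
})

test_that("PLSC singular values satisfy the Frobenius identity and rank bound", {
  tb <- toy_blocks(30, 4, 3, seed = 15)
  f <- fit_plsc(tb$X, tb$Y, k = 3)
  Xc <- scale(tb$X$values, scale = FALSE)
  Yc <- scale(tb$Y$values, scale = FALSE)
  Sxy <- crossprod(Xc, Yc) / 29
  expect_equal(sum(f$assoc^2), sum(Sxy^2), tolerance = 1e-8)

  # rank-deficient cross-covariance: k beyond rank errors
  y1 <- data_block(cbind(tb$Y$values[, 1]), tb$Y$sample_ids, "only")
  Ydup <- data_block(cbind(y1$values, 2 * y1$values),
                     tb$Y$sample_ids, c("a", "b"))
  expect_error(fit_plsc(tb$X, Ydup, k = 2), regexp = "rank",
               class = "cd_validation_error")
})

test_that("on whitened blocks PLSC coincides with CCA", {
  tb <- toy_blocks(40, 3, 2, seed = 16)
  Xw <- whiten_block(tb$X)
  Yw <- whiten_block(tb$Y)
  fc <- fit_cca(Xw, Yw, k = 2)
  fp <- fit_plsc(Xw, Yw, k = 2)
  expect_equal(unname(fc$assoc), unname(fp$assoc), tolerance = 1e-6)
  expect_lt(max_diff_signed(fc$U, fp$U), 1e-6)
  expect_lt(max_diff_signed(fc$V, fp$V), 1e-6)
})

test_that("PLSR first component equals PLSC's and the full fit matches NIPALS", {
  tb <- toy_blocks(25, 4, 3, seed = 17)
  fp <- fit_plsc(tb$X, tb$Y, k = 1)
  fr <- fit_plsr(tb$X, tb$Y, k = 1)
  expect_lt(max_diff_signed(cbind(fp$U[, 1]), cbind(fr$details$W[, 1])), 1e-8)

  fr3 <- fit_plsr(tb$X, tb$Y, k = 3)
  o <- oracle_pls2(tb$X, tb$Y, 3)
  expect_lt(max_diff_signed(o$W, fr3$details$W), 1e-6)
  expect_lt(max_diff_signed(o$T, fr3$T), 1e-6)
  expect_lt(max(abs(o$B - fr3$details$B)), 1e-6)

  # scores follow the deflation recurrence AND equal X %*% U (rotations)
  Xc <- scale(tb$X$values, scale = FALSE)
  expect_lt(max(abs(Xc %*% fr3$U - fr3$T)), 1e-8)
})

test_that("full-rank single-response PLSR reproduces OLS", {
  set.seed(18)
  X <- rand_block(30, 4, seed = 18)
  y <- data_block(cbind(X$values %*% c(1, -2, 0.5, 3) + rnorm(30)),
                  X$sample_ids, "y")
  f <- fit_plsr(X, y, k = 4)
  ols <- coef(lm(y$values ~ X$values))[-1]
  expect_equal(unname(drop(f$details$B)), unname(ols), tolerance = 1e-6)
  # and predictions agree with the linear model
  pred <- predict(f, X)
  expect_equal(unname(drop(pred)), unname(fitted(lm(y$values ~ X$values))),
               tolerance = 1e-6)
})

test_that("PLSR deflation exhausts X at k = rank(X)", {
  tb <- toy_blocks(20, 3, 3, seed = 19)
  f <- fit_plsr(tb$X, tb$Y, k = 3)
  expect_lt(max(abs(f$details$deflated_x)), 1e-6)
  expect_error(fit_plsr(tb$X, tb$Y, k = 4), regexp = "rank",
               class = "cd_validation_error")
})

test_that("structure coefficients are bounded, exact in the scalar case, and match a direct loop", {
  x <- rand_block(15, 1, seed = 20)
  y <- rand_block(15, 1, seed = 21, prefix = "Y")
  f <- fit_plsc(x, y, k = 1)
  expect_equal(abs(unname(f$x_loadings[1, 1])), 1, tolerance = 1e-10)

  tb <- toy_blocks(20, 3, 2, seed = 22)
  for (method in c("CCA", "PLSC", "PLSR")) {
    f <- fit_method(tb$X, tb$Y, method, k = 2)
    expect_true(all(abs(f$x_loadings) <= 1 + 1e-12))
    expect_true(all(abs(f$y_loadings) <= 1 + 1e-12))
    direct <- matrix(0, 3, 2)
    for (j in 1:3) for (c in 1:2)
      direct[j, c] <- cor(tb$X$values[, j], f$T[, c])
    expect_lt(max(abs(direct - f$x_loadings)), 1e-10)
  }
  expect_error(structure_coefficients(f, tb$Y, tb$X),
               class = "cd_validation_error")
})

test_that("fits are deterministic and follow the sign convention", {
  tb <- toy_blocks(35, 5, 4, seed = 23)
  for (method in c("CCA", "PLSC", "PLSR")) {
    f1 <- fit_method(tb$X, tb$Y, method)
    f2 <- fit_method(tb$X, tb$Y, method)
    expect_identical(f1$U, f2$U)
    expect_identical(f1$T, f2$T)
    expect_identical(f1$assoc, f2$assoc)
    # largest-|entry| of each y-weight column is positive
    for (c in seq_len(f1$k))
      expect_gt(f1$V[which.max(abs(f1$V[, c])), c], 0)
  }
  expect_error(fit_method(tb$X, tb$Y, "ICA"), regexp = "unknown",
               class = "cd_validation_error")
})
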