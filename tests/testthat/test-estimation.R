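# OLS, contrast tests, penalized fits, and cross-validated weight selection.

test_that("exact and closed-form cases come out exactly", {
  X <- cbind("(Intercept)" = 1, x = c(0, 1, 2))
  f <- fit_ols(X, c(0, 2, 4))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-12)

  set.seed(4)
  y <- rnorm(30)
  f0 <- fit_ols(matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f0$coefficients), mean(y), tolerance = 1e-12)
  expect_equal(unname(f0$standard_errors), sd(y) / sqrt(30), tolerance = 1e-12)
})

test_that("every reported statistic matches the pseudo-inverse oracle", {
  set.seed(101)
  inst <- random_instance(50, 4)
  f <- fit_ols(inst$X, inst$y)
  o <- oracle_ols(inst$X, inst$y)
  expect_equal(unname(f$coefficients), o$coefficients, tolerance = 1e-8)
  expect_equal(unname(f$standard_errors), o$standard_errors, tolerance = 1e-8)
  expect_equal(unname(f$t_values), o$t_values, tolerance = 1e-8)
  expect_equal(unname(f$p_values), o$p_values, tolerance = 1e-8)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-8)
  expect_equal(f$f_statistic$value, o$f_statistic, tolerance = 1e-8)
  expect_equal(f$log_likelihood, o$log_likelihood, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear messages", {
  X <- cbind("(Intercept)" = 1, x = rnorm(3))
  expect_error(fit_ols(X[1:2, ], rnorm(2)), "not enough datapoints")
  expect_error(fit_ols(cbind(X, x2 = X[, 2]), rnorm(3)), "not enough datapoints")
  expect_error(fit_ols(X, rep(1, 3)), "zero variance")
  Xs <- cbind("(Intercept)" = 1, a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_ols(Xs, c(1, 2, 3, 5)), "singular")
})

test_that("OLS is scale-equivariant in the predictors", {
  set.seed(7)
  inst <- random_instance(40, 3)
  f1 <- fit_ols(inst$X, inst$y)
  X2 <- inst$X
  X2[, 2] <- X2[, 2] * 10
  f2 <- fit_ols(X2, inst$y)
  expect_equal(unname(f2$coefficients[2]) * 10, unname(f1$coefficients[2]),
               tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("a single-df contrast has F = t^2 and exact fits report F = Inf", {
  dat <- balanced_oneway(c(10, 12), reps = 10L)
  set.seed(12)
  y <- dat$y + rnorm(20, sd = 0.3)
  cm <- coding_matrix("treatment", levels(dat$g))
  X <- cbind("(Intercept)" = 1, "g[B-A]" = encode_factor(dat$g, cm)[, 1])
  design <- list(term_map = list(g = 2L), factor_codings = list(g = cm))
  f <- fit_ols(X, y)
  ct <- contrast_test(f, design, "g")
  expect_equal(ct$f_value, unname(f$t_values[2])^2, tolerance = 1e-10)

  f0 <- fit_ols(X, dat$y)   # noiseless: exact fit
  ct0 <- contrast_test(f0, design, "g")
  expect_identical(ct0$f_value, Inf)
  expect_identical(ct0$p_value, 0)
  expect_equal(ct0$table$estimate, 2, tolerance = 1e-10)
  expect_error(contrast_test(f, design, "ghost"), "no coded columns")
})

test_that("ridge at weight 0 equals OLS and huge weights shrink slopes to zero", {
  set.seed(21)
  inst <- random_instance(40, 4)
  b0 <- fit_ridge(inst$X, inst$y, 0)
  expect_equal(unname(b0), unname(fit_ols(inst$X, inst$y)$coefficients),
               tolerance = 1e-10)
  binf <- fit_ridge(inst$X, inst$y, 1e12)
  expect_equal(unname(binf[-1]), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(binf[1]), mean(inst$y), tolerance = 1e-6)
  expect_error(fit_ridge(inst$X, inst$y, -1), "must be >= 0")
})

test_that("ridge matches an independently coded closed form", {
  set.seed(22)
  inst <- random_instance(40, 4)
  lambda <- 2.5
  # independent oracle: eigendecomposition on centered/scaled data
  X0 <- inst$X[, -1]
  n <- nrow(X0)
  mx <- colMeans(X0)
  s <- sqrt(colMeans(scale(X0, center = TRUE, scale = FALSE)^2))
  Z <- scale(X0, center = mx, scale = s)
  yc <- inst$y - mean(inst$y)
  eg <- eigen(crossprod(Z), symmetric = TRUE)
  bz <- eg$vectors %*% ((t(eg$vectors) %*% crossprod(Z, yc)) /
                          (eg$values + lambda))
  slopes <- drop(bz) / s
  icpt <- mean(inst$y) - sum(slopes * mx)
  expect_equal(unname(fit_ridge(inst$X, inst$y, lambda)),
               unname(c(icpt, slopes)), tolerance = 1e-8)
})

test_that("lasso reduces to OLS at weight 0 and soft-thresholds orthonormal designs", {
  set.seed(31)
  inst <- random_instance(60, 4)
  expect_equal(unname(fit_lasso(inst$X, inst$y, 0)),
               unname(fit_ols(inst$X, inst$y)$coefficients), tolerance = 1e-6)

  # columns orthonormal to each other AND to the intercept: Z'Z / n = I,
  # colMeans(Z) = 0, so internal standardization is the identity
  n <- 80
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  Z <- Q * sqrt(n)
  colnames(Z) <- paste0("z", 1:3)
  X <- cbind("(Intercept)" = 1, Z)
  y <- drop(Z %*% c(2, -0.5, 0.05)) + rnorm(n, 0, 0.2)
  lambda <- 0.3
  b <- fit_lasso(X, y, lambda)
  rho <- drop(crossprod(Z, y - mean(y))) / n
  expect_equal(unname(b[-1]), unname(sign(rho) * pmax(abs(rho) - lambda, 0)),
               tolerance = 1e-6)
})

test_that("all slopes vanish exactly at and beyond lambda_max", {
  set.seed(33)
  inst <- random_instance(50, 5)
  X0 <- inst$X[, -1]
  Z <- scale(X0, center = TRUE, scale = FALSE)
  Z <- sweep(Z, 2, sqrt(colMeans(Z^2)), "/")
  lambda_max <- max(abs(crossprod(Z, inst$y - mean(inst$y)))) / nrow(Z)
  b <- fit_lasso(inst$X, inst$y, lambda_max)
  expect_identical(unname(b[-1]), rep(0, 4))
  b2 <- fit_lasso(inst$X, inst$y, lambda_max * 1.5)
  expect_identical(unname(b2[-1]), rep(0, 4))
  b3 <- fit_lasso(inst$X, inst$y, lambda_max * 0.8)
  expect_gt(max(abs(b3[-1])), 0)
})

test_that("lasso agrees with glmnet as an independent cross-check", {
  skip_if_not_installed("glmnet")
  set.seed(35)
  inst <- random_instance(80, 6)
  lambda <- 0.7
  ours <- fit_lasso(inst$X, inst$y, lambda, tol = 1e-10)
  g <- glmnet::glmnet(inst$X[, -1], inst$y, lambda = lambda,
                      standardize = TRUE, thresh = 1e-14)
  theirs <- c(as.numeric(g$a0), as.numeric(g$beta))
  expect_equal(unname(ours), theirs, tolerance = 1e-4)
})

test_that("penalized coefficient norms are monotone non-increasing in the weight", {
  set.seed(41)
  inst <- random_instance(60, 5)
  grid <- default_weight_grid(12)
  for (fitter in list(fit_ridge, fit_lasso)) {
    norms <- vapply(grid, function(l) sum(abs(fitter(inst$X, inst$y, l)[-1])),
                    numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("weight selection is seeded, deterministic, and covers the grid", {
  set.seed(51)
  inst <- random_instance(60, 4)
  grid <- default_weight_grid(8)
  a <- select_weight(inst$X, inst$y, "L2", grid, seed = 10)
  b <- select_weight(inst$X, inst$y, "L2", grid, seed = 10)
  expect_identical(a$chosen_weight, b$chosen_weight)
  expect_identical(a$cv_curve, b$cv_curve)
  expect_identical(nrow(a$cv_curve), length(grid))
  expect_true(a$chosen_weight %in% grid)

  one <- select_weight(inst$X, inst$y, "L1", grid = 0.5, seed = 1)
  expect_identical(one$chosen_weight, 0.5)
  expect_error(select_weight(inst$X[1:5, ], inst$y[1:5], "L1", grid,
                             folds = 10), "fewer folds")
})

test_that("a noiseless linear truth selects the smallest grid weight", {
  set.seed(52)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(50), x2 = rnorm(50))
  y <- drop(X %*% c(1, 2, -1))
  sel <- select_weight(X, y, "L2", grid = c(0.001, 1, 1000), seed = 4)
  expect_identical(sel$chosen_weight, 0.001)
})
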