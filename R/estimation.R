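# Estimation: ordinary least squares with full inferential output, joint
# contrast F-tests, closed-form ridge, cyclic coordinate-descent lasso, and
# 10-fold cross-validated selection of the regularization weight.

# run code with the global RNG stream saved/restored, seeded locally
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit ordinary least squares with full inferential output
#'
#' Solves the normal equations and reports, per coefficient, the estimate,
#' standard error, t value and two-sided p value, and at the model level the
#' residual standard deviation, R^2, adjusted R^2, the overall F statistic
#' over all non-intercept coefficients, and the Gaussian log-likelihood
#' \eqn{-n/2 (\log 2\pi + \log(RSS/n) + 1)}.
#'
#' @param X Numeric design matrix (n x p, full rank, first column typically
#'   the intercept), with column names.
#' @param y Numeric response of length n (`n > p` required).
#' @return Object of class `nidm_ols`: `coefficients`, `standard_errors`,
#'   `t_values`, `p_values`, `residual_sd`, `r_squared`, `adj_r_squared`,
#'   `f_statistic` (with `df_model`, `df_residual`, `p_value`),
#'   `log_likelihood`, `n`, `p`, `fitted`, `residuals`, `XtX_inv`, `sigma2`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= p) {
    stop(sprintf("not enough datapoints: n = %d rows for p = %d coefficients (need n > p)",
                 n, p), call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("response has zero variance; R^2 is undefined", call. = FALSE)
  }
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) {
    stop("X'X is singular; the design matrix is not full rank", call. = FALSE)
  })
  beta <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  r2 <- 1 - rss / tss
  has_icpt <- "(Intercept)" %in% colnames(X)
  df_model <- p - as.integer(has_icpt)
  fstat <- if (df_model > 0L) {
    ((tss - rss) / df_model) / sigma2
  } else NA_real_
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  structure(list(
    coefficients = beta, standard_errors = se, t_values = tval,
    p_values = pval, residual_sd = sqrt(sigma2), r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / df_res,
    f_statistic = list(value = fstat, df_model = df_model,
                       df_residual = df_res,
                       p_value = if (df_model > 0L)
                         stats::pf(fstat, df_model, df_res, lower.tail = FALSE)
                       else NA_real_),
    log_likelihood = loglik, n = n, p = p,
    fitted = fitted, residuals = resid, XtX_inv = XtX_inv, sigma2 = sigma2,
    rss = rss),
    class = "nidm_ols")
}

#' Joint contrast test for one model factor
#'
#' Reports the OLS rows (estimate, SE, t, p) for the factor's coded columns
#' and the joint F test
#' \eqn{F = (C\hat\beta)' [C (X'X)^{-1} C']^{-1} (C\hat\beta) / (q \hat\sigma^2)}
#' where C selects the factor's q columns, compared with F(q, n-p). A
#' single-degree-of-freedom contrast satisfies F = t^2. An exact fit
#' (RSS = 0) is reported as F = Inf, p = 0.
#'
#' @param fit A [fit_ols()] result for the design.
#' @param design The [build_design()] object the fit came from.
#' @param variable Factor token to test; it must appear as a main-effect term
#'   (or interaction label) in the design's `term_map`.
#' @return Object of class `nidm_contrast`: `variable`, `scheme`, `table`
#'   (per-contrast rows), `f_value`, `df1`, `df2`, `p_value`.
#' @export
contrast_test <- function(fit, design, variable) {
  if (!variable %in% names(design$term_map)) {
    stop(sprintf("variable '%s' has no coded columns in the design", variable),
         call. = FALSE)
  }
  idx <- design$term_map[[variable]]
  q <- length(idx)
  b <- fit$coefficients[idx]
  V <- fit$XtX_inv[idx, idx, drop = FALSE]
  tab <- data.frame(
    contrast = names(fit$coefficients)[idx],
    estimate = unname(b),
    std_error = unname(fit$standard_errors[idx]),
    t_value = unname(fit$t_values[idx]),
    p_value = unname(fit$p_values[idx]),
    stringsAsFactors = FALSE)
  # an exact fit (RSS = 0 up to roundoff) is the sigma -> 0 limit: F = Inf
  exact <- fit$rss <= 1e-10 * sum((fit$fitted - mean(fit$fitted))^2)
  fval <- if (exact) {
    Inf
  } else {
    drop(crossprod(b, solve(V, b))) / (q * fit$sigma2)
  }
  scheme <- if (!is.null(design$factor_codings[[variable]])) {
    attr(design$factor_codings[[variable]], "scheme")
  } else {
    "numeric"
  }
  structure(list(variable = variable, scheme = scheme, table = tab,
                 f_value = fval, df1 = q, df2 = fit$f_statistic$df_residual,
                 p_value = if (is.infinite(fval)) 0 else
                   stats::pf(fval, q, fit$f_statistic$df_residual,
                             lower.tail = FALSE)),
            class = "nidm_contrast")
}

# center y, center + scale non-intercept predictors to unit population sd
# (divisor n), returning the pieces needed to map coefficients back
.standardize <- function(X, y) {
  icpt <- which(colnames(X) == "(Intercept)")
  Xs <- if (length(icpt)) X[, -icpt, drop = FALSE] else X
  n <- nrow(Xs)
  mx <- colMeans(Xs)
  Z <- sweep(Xs, 2L, mx, "-")
  s <- sqrt(colSums(Z^2) / n)
  if (any(s == 0)) {
    stop(sprintf("constant predictor column(s) cannot be standardized: %s",
                 paste(colnames(Xs)[s == 0], collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(Z, 2L, s, "/")
  list(Z = Z, yc = y - mean(y), my = mean(y), mx = mx, s = s,
       names = colnames(Xs))
}

.unstandardize <- function(bz, std) {
  slopes <- bz / std$s
  icpt <- std$my - sum(slopes * std$mx)
  stats::setNames(c(icpt, slopes), c("(Intercept)", std$names))
}

#' Ridge (L2) regression at a fixed weight
#'
#' Predictors are standardized internally (unit variance; the intercept is
#' unpenalized and recovered from centered data); the slopes solve
#' \eqn{(Z'Z + \lambda I)^{-1} Z'y} in standardized space and are returned on
#' the original scale. `weight = 0` reproduces [fit_ols()] coefficients.
#'
#' @param X Design matrix including an `"(Intercept)"` column.
#' @param y Numeric response.
#' @param weight Penalty \eqn{\lambda \ge 0}.
#' @return Named coefficient vector on the original scale.
#' @export
fit_ridge <- function(X, y, weight) {
  if (weight < 0) stop("regularization weight must be >= 0", call. = FALSE)
  std <- .standardize(X, y)
  A <- crossprod(std$Z)
  diag(A) <- diag(A) + weight
  bz <- drop(solve(A, crossprod(std$Z, std$yc)))
  .unstandardize(bz, std)
}

#' Lasso (L1) regression at a fixed weight
#'
#' Minimizes \eqn{\frac{1}{2n}\lVert y - X\beta\rVert^2 +
#' \lambda \lVert \beta_{-0} \rVert_1} on standardized predictors by cyclic
#' coordinate descent with soft-thresholding; the intercept is unpenalized.
#' Convergence when the largest coefficient change in a sweep falls below
#' `tol`, or after `max_sweeps` sweeps (then a warning reports the count).
#' With this scaling all slopes are exactly zero once
#' \eqn{\lambda \ge \max_j |z_j' y_c| / n}.
#'
#' @inheritParams fit_ridge
#' @param tol Convergence threshold on the maximum coefficient change
#'   (standardized scale); default `1e-6`.
#' @param max_sweeps Sweep cap; default `1e4`.
#' @return Named coefficient vector on the original scale.
#' @export
fit_lasso <- function(X, y, weight, tol = 1e-6, max_sweeps = 1e4) {
  if (weight < 0) stop("regularization weight must be >= 0", call. = FALSE)
  std <- .standardize(X, y)
  Z <- std$Z
  n <- nrow(Z)
  p <- ncol(Z)
  b <- numeric(p)
  r <- std$yc                     # residual for current b
  zz <- colSums(Z^2) / n          # = 1 by construction; kept for clarity
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      rho <- sum(Z[, j] * r) / n + zz[j] * b[j]
      bj_new <- sign(rho) * max(abs(rho) - weight, 0) / zz[j]
      d <- bj_new - b[j]
      if (d != 0) {
        r <- r - Z[, j] * d
        b[j] <- bj_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
    if (sweeps >= max_sweeps) {
      warning(sprintf("lasso coordinate descent did not converge within %d sweeps (last max change %.3g)",
                      sweeps, delta_max))
      break
    }
  }
  .unstandardize(b, std)
}

#' Default regularization weight grid
#'
#' @param n_points Number of grid points (default 30).
#' @param range Two-element numeric range covered log-uniformly
#'   (default `c(1e-3, 1e3)`, "a wide range").
#' @return Increasing numeric vector of weights.
#' @export
default_weight_grid <- function(n_points = 30L, range = c(1e-3, 1e3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n_points))
}

#' Select the regularization weight by 10-fold cross-validation
#'
#' Rows are partitioned into `folds` folds by a seeded shuffle. For every
#' weight in the grid the model is fit on the training folds and scored by
#' the held-out Gaussian log-likelihood, using the training residual variance
#' (MLE) as the noise variance. The chosen weight maximizes the mean held-out
#' log-likelihood per observation; ties break toward the larger (more
#' parsimonious) weight. The final coefficients are refit on all rows at the
#' chosen weight.
#'
#' @param X Design matrix including the intercept column.
#' @param y Numeric response (`length(y) >= folds`).
#' @param penalty `"L1"` (lasso) or `"L2"` (ridge).
#' @param grid Weight grid; defaults to [default_weight_grid()].
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold shuffle (the global RNG state is
#'   left untouched).
#' @return Object of class `nidm_penfit`: `penalty`, `chosen_weight`,
#'   `coefficients` (original scale, refit on all data), `cv_curve` (data
#'   frame `weight`, `cv_loglik`, `cv_mse` covering the whole grid), `folds`,
#'   `seed`.
#' @export
select_weight <- function(X, y, penalty = c("L1", "L2"),
                          grid = default_weight_grid(), folds = 10L,
                          seed = 1L) {
  penalty <- match.arg(penalty)
  n <- length(y)
  if (n < folds) {
    stop(sprintf("n = %d is smaller than the number of folds (%d); use fewer folds",
                 n, folds), call. = FALSE)
  }
  grid <- sort(as.numeric(grid))
  fit_fun <- if (penalty == "L1") fit_lasso else fit_ridge
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  ll <- matrix(NA_real_, length(grid), folds)
  mse <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]
    yte <- y[test]
    for (g in seq_along(grid)) {
      b <- fit_fun(Xtr, ytr, grid[g])
      res_tr <- ytr - drop(Xtr %*% b[colnames(Xtr)])
      s2 <- sum(res_tr^2) / length(ytr)
      pred <- drop(Xte %*% b[colnames(Xte)])
      ll[g, f] <- sum(stats::dnorm(yte, pred, sqrt(s2), log = TRUE))
      mse[g, f] <- mean((yte - pred)^2)
    }
  }
  cv_loglik <- rowSums(ll) / n       # mean held-out log-likelihood per row
  cv_mse <- rowSums(mse * tabulate(fold_id, folds)[col(mse)]) / n
  best <- max(which(cv_loglik == max(cv_loglik)))  # ties -> larger weight
  structure(list(penalty = penalty, chosen_weight = grid[best],
                 coefficients = fit_fun(X, y, grid[best]),
                 cv_curve = data.frame(weight = grid, cv_loglik = cv_loglik,
                                       cv_mse = cv_mse),
                 folds = folds, seed = seed),
            class = "nidm_penfit")
}

#' @export
print.nidm_penfit <- function(x, ...) {
  cat(sprintf("%s-regularized fit: weight %.6g chosen by %d-fold cross-validation\n",
              x$penalty, x$chosen_weight, x$folds))
  cat(sprintf("  mean held-out log-likelihood at the chosen weight: %.4f\n",
              x$cv_curve$cv_loglik[match(x$chosen_weight, x$cv_curve$weight)]))
  cat("coefficients:\n")
  print(round(x$coefficients, 6))
  invisible(x)
}
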