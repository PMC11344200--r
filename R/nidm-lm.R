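# The user-facing model fit: documents in, fitted model object out.

#' Fit a linear model to NIDM-lite study documents
#'
#' Runs the full pipeline: read the study documents, parse the model string,
#' resolve every variable reference (element id, study-local name, or concept
#' URL) in every document, pool subjects across documents into one table
#' (listwise deletion of subjects with missing values), build the design
#' matrix with the requested contrast codings, fit ordinary least squares
#' with full inference, run the joint contrast F-test for each contrast
#' variable, and — if requested — fit the L1/L2-regularized model with the
#' penalty weight chosen by 10-fold cross-validated held-out likelihood.
#'
#' Fewer than `min_n` pooled datapoints triggers a warning that the result
#' will be less accurate (the command-line front end additionally asks for
#' confirmation; see [run_linear_regression()]).
#'
#' @param model Model string, e.g.
#'   `"fs_000008 = DX_GROUP + PIQ_tca9ck + http://uri.interlex.org/ilx_0100400"`.
#'   `=` and `~` are interchangeable; `*` inside a term builds only the
#'   product (interaction) column block.
#' @param docs Study documents: paths to NIDM-lite Turtle files, `nidm_study`
#'   objects, or a list of either.
#' @param contrast Contrast variables (comma-separated string or character
#'   vector), or `NULL` for none.
#' @param coding Contrast coding scheme for the contrast variables:
#'   `"treatment"` (default), `"simple"`, `"sum"`, `"backward_difference"`,
#'   or `"helmert"`. Non-contrast categorical factors always use treatment
#'   coding with the first declared level as reference.
#' @param regularization `"none"` (default), `"L1"` (lasso), or `"L2"`
#'   (ridge).
#' @param grid Regularization weight grid; defaults to
#'   [default_weight_grid()].
#' @param folds Cross-validation folds for weight selection (default 10).
#' @param seed Seed for the cross-validation fold shuffle (default 1).
#' @param min_n Datapoint count below which a small-sample warning is issued
#'   (default 20).
#' @return Object of class `nidm_lm` with components `spec`, `table`,
#'   `design`, `fit` (the [fit_ols()] result), `contrasts` (list of
#'   [contrast_test()] results), `penalized` (a `nidm_penfit` or `NULL`),
#'   `n_dropped_missing`, `documents` (per-document subject counts), and
#'   `call`.
#' @examples
#' docs <- generate_multisite(seed = 7)
#' fit <- nidm_lm("fs_000008 = DX_GROUP + PIQ_tca9ck + http://uri.interlex.org/ilx_0100400",
#'                docs, contrast = "DX_GROUP")
#' summary(fit)
#' @export
nidm_lm <- function(model, docs, contrast = NULL, coding = "treatment",
                    regularization = c("none", "L1", "L2"),
                    grid = default_weight_grid(), folds = 10L, seed = 1L,
                    min_n = 20L) {
  cl <- match.call()
  spec <- model_spec(model, contrast, coding, regularization)
  docs <- as_nidm_docs(docs)
  refs <- unique(c(spec$dv$token, unlist(spec$terms)))
  dat <- extract_table(docs, refs)
  n <- nrow(dat)
  if (n < min_n) {
    warning(sprintf("only %d datapoints (fewer than %d): the result will not be as accurate",
                    n, min_n), call. = FALSE)
  }
  design <- build_design(dat, spec)
  if (n <= ncol(design$X)) {
    stop(sprintf("not enough datapoints: n = %d for p = %d model columns", n,
                 ncol(design$X)), call. = FALSE)
  }
  fit <- fit_ols(design$X, design$y)
  contrasts <- lapply(spec$contrast_vars, function(v)
    contrast_test(fit, design, v))
  names(contrasts) <- spec$contrast_vars
  penalized <- if (spec$regularization != "none") {
    select_weight(design$X, design$y, penalty = spec$regularization,
                  grid = grid, folds = folds, seed = seed)
  }
  docs_tab <- table(factor(dat$document_id, levels = names(docs)))
  structure(list(spec = spec, table = dat, design = design, fit = fit,
                 contrasts = contrasts, penalized = penalized,
                 n_dropped_missing = attr(dat, "n_dropped_missing"),
                 documents = stats::setNames(as.integer(docs_tab),
                                             names(docs_tab)),
                 call = cl),
            class = "nidm_lm")
}

#' @export
print.nidm_lm <- function(x, ...) {
  cat("Linear model on NIDM-lite documents\n")
  cat("  model:", render_model(x$spec), "\n")
  cat(sprintf("  n = %d subject(s) pooled from %d document(s) (%d dropped for missing values)\n",
              x$fit$n, length(x$documents), x$n_dropped_missing))
  cat("coefficients:\n")
  print(round(x$fit$coefficients, 6))
  if (!is.null(x$penalized)) {
    cat(sprintf("%s regularization: chosen weight %.6g\n",
                x$penalized$penalty, x$penalized$chosen_weight))
  }
  invisible(x)
}

#' @export
coef.nidm_lm <- function(object, ...) object$fit$coefficients

#' @export
residuals.nidm_lm <- function(object, ...) object$fit$residuals

#' @export
fitted.nidm_lm <- function(object, ...) object$fit$fitted

#' @export
logLik.nidm_lm <- function(object, ...) {
  structure(object$fit$log_likelihood, df = object$fit$p + 1L,
            nobs = object$fit$n, class = "logLik")
}

#' @export
confint.nidm_lm <- function(object, parm, level = 0.95, ...) {
  f <- object$fit
  q <- stats::qt((1 + level) / 2, f$f_statistic$df_residual)
  ci <- cbind(f$coefficients - q * f$standard_errors,
              f$coefficients + q * f$standard_errors)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# rebuild design columns for new raw data, reusing the stored codings
.design_rows <- function(object, newdata) {
  spec <- object$spec
  info <- attr(object$table, "column_info")
  n <- nrow(newdata)
  blocks <- list(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  for (term in spec$terms) {
    parts <- lapply(term, function(tok) {
      if (!tok %in% names(newdata)) {
        stop(sprintf("newdata lacks model variable '%s'", tok), call. = FALSE)
      }
      if (info[[tok]]$value_type == "numeric") {
        matrix(as.numeric(newdata[[tok]]), ncol = 1L,
               dimnames = list(NULL, tok))
      } else {
        cm <- object$design$factor_codings[[tok]]
        Z <- encode_factor(newdata[[tok]], cm)
        colnames(Z) <- paste0(tok, "[", colnames(cm), "]")
        Z
      }
    })
    blocks[[length(blocks) + 1L]] <- Reduce(function(A, B) {
      cols <- list()
      for (a in seq_len(ncol(A))) for (b in seq_len(ncol(B))) {
        cols[[length(cols) + 1L]] <- A[, a] * B[, b]
        names(cols)[length(cols)] <- paste(colnames(A)[a], colnames(B)[b],
                                           sep = ":")
      }
      do.call(cbind, cols)
    }, parts)
  }
  X <- do.call(cbind, blocks)
  X[, object$design$column_names, drop = FALSE]
}

#' Predict from a fitted NIDM-lite linear model
#'
#' @param object A [nidm_lm()] fit.
#' @param newdata Data frame with one column per model variable (raw values:
#'   numeric for numeric elements, level labels for categorical ones). When
#'   omitted, fitted values are returned.
#' @param penalized Use the regularized coefficients instead of OLS (requires
#'   a fit with `regularization != "none"`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.nidm_lm <- function(object, newdata = NULL, penalized = FALSE, ...) {
  b <- if (penalized) {
    if (is.null(object$penalized)) {
      stop("model was fitted without regularization", call. = FALSE)
    }
    object$penalized$coefficients
  } else {
    object$fit$coefficients
  }
  if (is.null(newdata)) {
    return(drop(object$design$X %*% b[object$design$column_names]))
  }
  X <- .design_rows(object, newdata)
  drop(X %*% b[colnames(X)])
}

#' Simulate responses from a fitted NIDM-lite linear model
#'
#' Draws Gaussian responses at the fitted means with the residual standard
#' deviation.
#'
#' @param object A [nidm_lm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed (the global RNG state is preserved).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of length n.
#' @export
simulate.nidm_lm <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fit$fitted
  sd <- object$fit$residual_sd
  draw <- function() stats::rnorm(length(mu), mu, sd)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  stats::setNames(as.data.frame(sims), paste0("sim_", seq_len(nsim)))
}

#' Diagnostic plots for a fitted NIDM-lite linear model
#'
#' Residuals against fitted values and a normal Q-Q plot of the residuals.
#'
#' @param x A [nidm_lm()] fit.
#' @param which Subset of `1:2`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.nidm_lm <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    plot(x$fit$fitted, x$fit$residuals, xlab = "fitted values",
         ylab = "residuals", main = "Residuals vs fitted", ...)
    graphics::abline(h = 0, lty = 2)
  }
  if (2 %in% which) {
    stats::qqnorm(x$fit$residuals, main = "Normal Q-Q of residuals", ...)
    stats::qqline(x$fit$residuals)
  }
  invisible(x)
}

#' @export
summary.nidm_lm <- function(object, ...) {
  f <- object$fit
  coef_table <- data.frame(
    term = names(f$coefficients),
    estimate = unname(f$coefficients),
    std_error = unname(f$standard_errors),
    t_value = unname(f$t_values),
    p_value = unname(f$p_values),
    stringsAsFactors = FALSE)
  structure(list(model = render_model(object$spec),
                 documents = object$documents,
                 n = f$n, p = f$p,
                 n_dropped_missing = object$n_dropped_missing,
                 coefficients = coef_table,
                 residual_sd = f$residual_sd,
                 r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
                 f_statistic = f$f_statistic,
                 log_likelihood = f$log_likelihood,
                 contrasts = object$contrasts,
                 penalized = object$penalized),
            class = "summary.nidm_lm")
}

#' @export
print.summary.nidm_lm <- function(x, digits = 4, ...) {
  cat("Linear model on NIDM-lite documents\n")
  cat("model:", x$model, "\n")
  cat(sprintf("pooled n = %d (dropped for missing values: %d) across document(s): %s\n",
              x$n, x$n_dropped_missing,
              paste(sprintf("%s (%d)", names(x$documents), x$documents),
                    collapse = ", ")))
  cat("\nCoefficients:\n")
  cm <- as.matrix(x$coefficients[, -1])
  rownames(cm) <- x$coefficients$term
  colnames(cm) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")
  stats::printCoefmat(cm, digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual SD: %.*g on %d degrees of freedom\n", digits,
              x$residual_sd, x$f_statistic$df_residual))
  cat(sprintf("R-squared: %.*g, adjusted R-squared: %.*g\n", digits,
              x$r_squared, digits, x$adj_r_squared))
  if (!is.na(x$f_statistic$value)) {
    cat(sprintf("F-statistic: %.*g on %d and %d DF, p-value: %.4g\n", digits,
                x$f_statistic$value, x$f_statistic$df_model,
                x$f_statistic$df_residual, x$f_statistic$p_value))
  }
  cat(sprintf("log-likelihood: %.*g\n", digits + 2, x$log_likelihood))
  for (ct in x$contrasts) {
    cat(sprintf("\nContrast on '%s' (%s coding):\n", ct$variable, ct$scheme))
    cm <- as.matrix(ct$table[, -1])
    rownames(cm) <- ct$table$contrast
    colnames(cm) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")
    stats::printCoefmat(cm, digits = digits, P.values = TRUE, has.Pvalue = TRUE)
    cat(sprintf("joint F(%d, %d) = %.*g, p = %.4g\n", ct$df1, ct$df2, digits,
                ct$f_value, ct$p_value))
  }
  if (!is.null(x$penalized)) {
    pf <- x$penalized
    cat(sprintf("\n%s regularization (%d-fold cross-validation over %d weights):\n",
                pf$penalty, pf$folds, nrow(pf$cv_curve)))
    cat(sprintf("  chosen weight: %.6g\n", pf$chosen_weight))
    cat("  coefficients at the chosen weight:\n")
    print(round(pf$coefficients, 6))
  }
  invisible(x)
}
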