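# Report rendering: text, JSON, and CSV views of a fitted model.

# everything numeric the run produced, as a plain list (the JSON schema)
as_report_list <- function(object) {
  stopifnot(inherits(object, "nidm_lm"))
  s <- summary(object)
  out <- list(
    model = s$model,
    contrast = if (length(object$spec$contrast_vars))
      object$spec$contrast_vars else character(0),
    coding = object$spec$contrast_scheme,
    regularization = object$spec$regularization,
    n = s$n,
    p = s$p,
    n_dropped_missing = s$n_dropped_missing,
    documents = as.list(s$documents),
    coefficients = s$coefficients,
    residual_sd = s$residual_sd,
    r_squared = s$r_squared,
    adj_r_squared = s$adj_r_squared,
    f_statistic = s$f_statistic,
    log_likelihood = s$log_likelihood,
    contrasts = lapply(unname(s$contrasts), function(ct) {
      list(variable = ct$variable, scheme = ct$scheme, table = ct$table,
           f_value = ct$f_value, df1 = ct$df1, df2 = ct$df2,
           p_value = ct$p_value)
    })
  )
  if (!is.null(s$penalized)) {
    pf <- s$penalized
    out$penalized <- list(
      penalty = pf$penalty,
      chosen_weight = pf$chosen_weight,
      folds = pf$folds,
      coefficients = as.list(pf$coefficients),
      cv_curve = pf$cv_curve)
  }
  out
}

#' Render a fitted model as text, JSON, or CSV
#'
#' `"text"` gives the aligned coefficient / contrast / regularization tables
#' of `print(summary(fit))`. `"json"` gives the same content as a
#' machine-readable document (keys: `model`, `contrast`, `coding`,
#' `regularization`, `n`, `p`, `n_dropped_missing`, `documents`,
#' `coefficients`, `residual_sd`, `r_squared`, `adj_r_squared`,
#' `f_statistic`, `log_likelihood`, `contrasts`, and `penalized` with the
#' full cross-validation curve when regularization was requested). `"csv"`
#' gives the coefficient table only.
#'
#' @param object A [nidm_lm()] fit.
#' @param format `"text"`, `"json"`, or `"csv"`.
#' @return A character vector of report lines (length 1 for JSON).
#' @export
render_report <- function(object, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  switch(format,
    text = utils::capture.output(print(summary(object))),
    json = as.character(jsonlite::toJSON(as_report_list(object),
                                         auto_unbox = TRUE, digits = NA,
                                         dataframe = "columns", null = "null",
                                         pretty = TRUE)),
    csv = {
      tab <- summary(object)$coefficients
      con <- textConnection("csv_lines", "w", local = TRUE)
      utils::write.csv(tab, con, row.names = FALSE)
      close(con)
      csv_lines
    })
}
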