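# Design-matrix construction and categorical contrast codings.
#
# Each coding scheme is defined by its estimand contract on balanced one-way
# data with level means m1..mk:
#   treatment:           b_j = m_{j+1} - m_1              (intercept = m_1)
#   simple:              b_j = m_{j+1} - m_1              (intercept = grand mean)
#   sum:                 b_j = m_j     - mean(m)          (intercept = grand mean)
#   backward_difference: b_j = m_{j+1} - m_j              (intercept = grand mean)
#   helmert:             b_j = m_{j+1} - mean(m_1..m_j)   (intercept = grand mean)
# The k x (k-1) coding matrix is obtained by inverting the k x k hypothesis
# matrix (intercept row + the k-1 contrast rows above), which makes the
# contracts hold by construction rather than by convention-specific formulas.

# hypothesis rows as a (k x k) matrix: row 1 = intercept estimand,
# rows 2..k = contrast estimands, expressed as weights over level means
.hypothesis_matrix <- function(scheme, k) {
  H <- matrix(0, k, k)
  if (scheme == "treatment") H[1, 1] <- 1 else H[1, ] <- 1 / k
  for (j in seq_len(k - 1L)) {
    r <- j + 1L
    switch(scheme,
      treatment = ,
      simple = { H[r, 1] <- -1; H[r, j + 1L] <- 1 },
      sum = { H[r, ] <- -1 / k; H[r, j] <- H[r, j] + 1 },
      backward_difference = { H[r, j] <- -1; H[r, j + 1L] <- 1 },
      helmert = { H[r, seq_len(j)] <- -1 / j; H[r, j + 1L] <- 1 })
  }
  H
}

#' Build a contrast coding matrix
#'
#' Returns the k x (k-1) matrix that maps a k-level factor to k-1 regression
#' columns whose coefficients, on balanced one-way data, estimate the
#' scheme's documented mean contrasts (see Details).
#'
#' @details Contracts on balanced data with level means \eqn{m_1..m_k}:
#' treatment and simple code \eqn{m_{j+1} - m_1} (treatment puts \eqn{m_1} in
#' the intercept, simple the grand mean); sum codes \eqn{m_j - \bar m};
#' backward difference codes \eqn{m_{j+1} - m_j}; Helmert codes
#' \eqn{m_{j+1} - \mathrm{mean}(m_1..m_j)}, scaled so the regression
#' coefficient equals that mean difference exactly.
#'
#' @param scheme One of `"treatment"`, `"simple"`, `"sum"`,
#'   `"backward_difference"`, `"helmert"`.
#' @param levels Ordered character vector of category labels (k >= 2); the
#'   first level is the reference where the scheme has one.
#' @return Object of class `nidm_coding`: the coding matrix with level
#'   rownames and descriptive column names, plus attributes `scheme` and
#'   `levels`.
#' @examples
#' coding_matrix("sum", c("A", "B", "C"))
#' @export
coding_matrix <- function(scheme, levels) {
  scheme <- match.arg(scheme, CODING_SCHEMES)
  levels <- as.character(levels)
  k <- length(levels)
  if (k < 2L) stop("a coding needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels)) stop("duplicated levels", call. = FALSE)
  C <- solve(.hypothesis_matrix(scheme, k))[, -1L, drop = FALSE]
  C[abs(C) < 1e-12] <- 0
  rownames(C) <- levels
  colnames(C) <- vapply(seq_len(k - 1L), function(j) {
    switch(scheme,
      treatment = ,
      simple = paste0(levels[j + 1L], "-", levels[1L]),
      sum = paste0(levels[j], "-mean"),
      backward_difference = paste0(levels[j + 1L], "-", levels[j]),
      helmert = paste0(levels[j + 1L], "-mean(",
                       paste(levels[seq_len(j)], collapse = ","), ")"))
  }, character(1))
  structure(C, scheme = scheme, levels = levels, class = c("nidm_coding", "matrix"))
}

#' Apply a coding matrix to a categorical column
#'
#' @param values Character or factor vector; every value must be one of the
#'   coding's levels.
#' @param coding A [coding_matrix()].
#' @return Numeric matrix with `length(values)` rows and k-1 columns: row i
#'   is the coding-matrix row of the i-th value's level.
#' @export
encode_factor <- function(values, coding) {
  stopifnot(inherits(coding, "nidm_coding"))
  values <- as.character(values)
  idx <- match(values, attr(coding, "levels"))
  if (anyNA(idx)) {
    stop(sprintf("value '%s' is not among the declared levels (%s)",
                 values[which(is.na(idx))[1]],
                 paste(attr(coding, "levels"), collapse = ", ")), call. = FALSE)
  }
  out <- unclass(coding)[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# column block (matrix + names) for a single factor token
.factor_block <- function(table, spec, token, info) {
  x <- table[[token]]
  if (info$value_type == "numeric") {
    list(X = matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, token)),
         coding = NULL)
  } else {
    scheme <- if (token %in% spec$contrast_vars) spec$contrast_scheme else "treatment"
    cm <- coding_matrix(scheme, info$levels)
    Z <- encode_factor(x, cm)
    colnames(Z) <- paste0(token, "[", colnames(cm), "]")
    list(X = Z, coding = cm)
  }
}

#' Build the numeric design matrix for a model
#'
#' Numeric factors enter as single columns in raw units (no centering or
#' standardization at this stage). Categorical factors are expanded by a
#' coding matrix: contrast variables use the spec's scheme, all other
#' categorical factors use treatment coding with the element's first declared
#' level as reference. Interaction terms are the elementwise products of all
#' pairings of their factors' columns, named `"A:B"`.
#'
#' @param table An [extract_table()] result (or any data frame carrying a
#'   compatible `column_info` attribute).
#' @param spec A [model_spec()].
#' @return A list of class `nidm_design`: `X` (n x p numeric matrix whose
#'   first column is the intercept), `y` (numeric response), `term_map`
#'   (term label -> column indices), `factor_codings` (factor ->
#'   [coding_matrix()] used). Rank deficiency is a hard error listing the
#'   aliased columns.
#' @export
build_design <- function(table, spec) {
  info <- attr(table, "column_info")
  if (is.null(info)) stop("`table` lacks a column_info attribute; use extract_table()", call. = FALSE)
  dv_tok <- spec$dv$token
  if (!dv_tok %in% names(info)) stop(sprintf("dependent variable '%s' not in table", dv_tok), call. = FALSE)
  if (info[[dv_tok]]$value_type != "numeric") {
    stop(sprintf("dependent variable '%s' is categorical; the response must be numeric",
                 dv_tok), call. = FALSE)
  }
  y <- as.numeric(table[[dv_tok]])
  n <- nrow(table)

  blocks <- list(intercept = matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  factor_codings <- list()
  term_map <- list()
  col_at <- 1L
  for (term in spec$terms) {
    parts <- lapply(term, function(tok) {
      if (!tok %in% names(info)) stop(sprintf("model factor '%s' not in table", tok), call. = FALSE)
      b <- .factor_block(table, spec, tok, info[[tok]])
      if (!is.null(b$coding)) factor_codings[[tok]] <<- b$coding
      b$X
    })
    # all pairwise (generally q-way) products of one column from each factor
    prod_block <- Reduce(function(A, B) {
      cols <- list()
      for (a in seq_len(ncol(A))) {
        for (b in seq_len(ncol(B))) {
          cols[[length(cols) + 1L]] <- A[, a] * B[, b]
          names(cols)[length(cols)] <- paste(colnames(A)[a], colnames(B)[b], sep = ":")
        }
      }
      do.call(cbind, cols)
    }, parts)
    label <- paste(term, collapse = "*")
    term_map[[label]] <- seq.int(col_at + 1L, length.out = ncol(prod_block))
    col_at <- col_at + ncol(prod_block)
    blocks[[length(blocks) + 1L]] <- prod_block
  }
  X <- do.call(cbind, blocks)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("design matrix is rank deficient; linearly dependent column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  structure(list(X = X, y = y, term_map = term_map,
                 factor_codings = factor_codings,
                 column_names = colnames(X)),
            class = "nidm_design")
}
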