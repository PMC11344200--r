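# Model-string parsing.
#
# Syntax: "DV = IV1 + IV2 + IV1*IV2", with "=" and "~" interchangeable.
# "+" separates terms; "*" inside a term builds the product (interaction)
# column block ONLY — main effects are not implied and must be listed
# explicitly, as in "y = a + b + a*b".  All tokens are trimmed of
# surrounding whitespace, so spacing never changes the parsed model.

#' Parse a model string
#'
#' Splits on the first `=` or `~` (treated identically), splits the
#' right-hand side on `+`, and each summand on `*` into an interaction term.
#' `*` produces only the product term; main effects are taken literally from
#' the formula (a deliberate difference from R's `*` expansion).
#'
#' @param text Model string, e.g. `"fs_000008 = DX_GROUP + PIQ_tca9ck + age"`.
#' @return A list with `dv` (a [variable_ref()]) and `terms`, a list of
#'   character vectors of factor tokens (length 1 = main effect, length >= 2
#'   = interaction).
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty model string", call. = FALSE)
  sep <- regexpr("[=~]", text)
  if (sep == -1L) {
    stop("model string must contain '=' or '~' separating the dependent variable from the model terms",
         call. = FALSE)
  }
  lhs <- trimws(substr(text, 1L, sep - 1L))
  rhs <- trimws(substr(text, sep + 1L, nchar(text)))
  if (!nzchar(lhs)) stop("model string has no dependent variable before '='/'~'", call. = FALSE)
  if (!nzchar(rhs)) stop("model string has no independent variables after '='/'~'", call. = FALSE)
  terms <- lapply(strsplit(rhs, "+", fixed = TRUE)[[1]], function(summand) {
    factors <- trimws(strsplit(summand, "*", fixed = TRUE)[[1]])
    if (any(!nzchar(factors))) {
      stop(sprintf("empty token in model term '%s'", trimws(summand)), call. = FALSE)
    }
    if (anyDuplicated(factors)) {
      stop(sprintf("factor repeated within interaction term '%s'", trimws(summand)),
           call. = FALSE)
    }
    factors
  })
  if (length(terms) == 0L) stop("model has no terms", call. = FALSE)
  if (lhs %in% unlist(terms)) {
    stop(sprintf("the dependent variable '%s' also appears as an independent variable; this is impossible, halting",
                 lhs), call. = FALSE)
  }
  term_keys <- vapply(terms, paste, character(1), collapse = "*")
  if (anyDuplicated(term_keys)) {
    stop(sprintf("duplicated model term(s): %s",
                 paste(unique(term_keys[duplicated(term_keys)]), collapse = ", ")),
         call. = FALSE)
  }
  list(dv = variable_ref(lhs), terms = terms)
}

#' Parse a contrast variable list
#'
#' @param text Comma-separated tokens (empty string gives an empty list).
#' @param terms The `terms` component of [parse_model()]; every contrast
#'   token must appear there as a factor.
#' @return Character vector of contrast variable tokens.
#' @export
parse_contrast <- function(text, terms) {
  if (is.null(text) || !nzchar(trimws(text))) return(character(0))
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  factors <- unique(unlist(terms))
  for (tok in tokens) {
    if (!tok %in% factors) {
      stop(sprintf("contrast variable '%s' does not appear in the model", tok),
           call. = FALSE)
    }
  }
  unique(tokens)
}

CODING_SCHEMES <- c("treatment", "simple", "sum", "backward_difference", "helmert")

#' Assemble a validated model specification
#'
#' @param model Model string (see [parse_model()]).
#' @param contrast Comma-separated contrast variables, character vector, or
#'   `NULL`.
#' @param coding Contrast coding scheme applied to all contrast variables:
#'   one of `"treatment"`, `"simple"`, `"sum"`, `"backward_difference"`,
#'   `"helmert"`.
#' @param regularization `"none"`, `"L1"` (lasso), or `"L2"` (ridge).
#' @return Object of class `nidm_model_spec` with fields `dv`, `terms`,
#'   `contrast_vars`, `contrast_scheme`, `regularization`.
#' @export
model_spec <- function(model, contrast = NULL, coding = "treatment",
                       regularization = c("none", "L1", "L2")) {
  coding <- match.arg(coding, CODING_SCHEMES)
  regularization <- match.arg(regularization)
  parsed <- parse_model(model)
  contrast_vars <- if (is.character(contrast) && length(contrast) > 1L) {
    parse_contrast(paste(contrast, collapse = ","), parsed$terms)
  } else {
    parse_contrast(if (is.null(contrast)) "" else contrast, parsed$terms)
  }
  structure(list(dv = parsed$dv, terms = parsed$terms,
                 contrast_vars = contrast_vars, contrast_scheme = coding,
                 regularization = regularization),
            class = "nidm_model_spec")
}

#' Render a model specification back to canonical text
#'
#' @param spec A `nidm_model_spec`.
#' @return Canonical model string, e.g. `"y = x1 + x2 + x1*x2"`.
#' @export
render_model <- function(spec) {
  paste(spec$dv$token, "=",
        paste(vapply(spec$terms, paste, character(1), collapse = "*"),
              collapse = " + "))
}

#' @export
print.nidm_model_spec <- function(x, ...) {
  cat("model:", render_model(x), "\n")
  cat("contrast:", if (length(x$contrast_vars)) paste(x$contrast_vars, collapse = ", ") else "none", "\n")
  cat("coding:", x$contrast_scheme, "\n")
  cat("regularization:", x$regularization, "\n")
  invisible(x)
}

#' Echo the fully normalized command
#'
#' Renders the canonical form of a run configuration — whitespace stripped,
#' `~` canonicalized to `=`, the file list expanded — so the user can trace
#' syntax errors against what the tool actually understood. Printed before
#' any file is opened.
#'
#' @param files Character vector of document paths.
#' @param spec A `nidm_model_spec`.
#' @return Single canonical command string.
#' @export
normalize_command <- function(files, spec) {
  paste0("files: ", paste(files, collapse = ", "),
         " | model: ", render_model(spec),
         " | contrast: ", if (length(spec$contrast_vars))
           paste(spec$contrast_vars, collapse = ", ") else "none",
         " | coding: ", spec$contrast_scheme,
         " | regularization: ", spec$regularization)
}
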