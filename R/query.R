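# Variable resolution and table extraction.
#
# Users address variables in three forms: (1) the element identifier token,
# (2) the study-local source variable name, (3) a concept URL annotating the
# element.  A token starting with http:// or https:// is taken as a concept
# URL; otherwise element_id match is tried first, then source_variable.
# Matching is exact and case-sensitive.

#' Construct a variable reference
#'
#' @param token The raw string the user typed: an element id, a study-local
#'   variable name, or a concept URL.
#' @return An object of class `nidm_ref` with fields `token` and `form`
#'   (`"concept_url"` or `"token"`).
#' @export
variable_ref <- function(token) {
  token <- trimws(token)
  if (!nzchar(token)) stop("empty variable reference", call. = FALSE)
  structure(list(token = token,
                 form = if (grepl("^https?://", token)) "concept_url" else "token"),
            class = "nidm_ref")
}

as_variable_ref <- function(x) {
  if (inherits(x, "nidm_ref")) x else variable_ref(x)
}

#' Resolve a variable reference within one document
#'
#' Concept-URL references match elements annotated with that URL. Other
#' tokens try, in order, an exact `element_id` match, then an exact
#' `source_variable` match; the id form wins when both would match different
#' elements.
#'
#' @param doc A [nidm_study()].
#' @param ref A [variable_ref()] or character token.
#' @return The matching [nidm_element()], or `NULL` if no element matches.
#'   More than one match within the document is an error listing the
#'   candidate element ids.
#' @export
resolve_variable <- function(doc, ref) {
  ref <- as_variable_ref(ref)
  els <- doc$elements
  hits <- if (ref$form == "concept_url") {
    els[vapply(els, function(e) ref$token %in% e$concept_urls, logical(1))]
  } else {
    by_id <- els[vapply(els, function(e) identical(e$element_id, ref$token),
                        logical(1))]
    if (length(by_id)) {
      by_id
    } else {
      els[vapply(els, function(e) identical(e$source_variable, ref$token),
                 logical(1))]
    }
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    stop(sprintf("document '%s': reference '%s' is ambiguous; candidate elements: %s",
                 doc$document_id, ref$token,
                 paste(vapply(hits, function(e) e$element_id, character(1)),
                       collapse = ", ")), call. = FALSE)
  }
  hits[[1]]
}

#' Report variable references that documents cannot resolve
#'
#' @param docs Documents (see [list_data_elements()] for accepted forms).
#' @param refs Character vector of reference tokens or [variable_ref()]s.
#' @return Data frame (`document_id`, `token`) with one row per unresolved
#'   reference; zero rows when every reference resolves everywhere.
#' @export
missing_report <- function(docs, refs) {
  docs <- as_nidm_docs(docs)
  refs <- lapply(refs, as_variable_ref)
  rows <- list()
  for (d in docs) {
    for (r in refs) {
      if (is.null(resolve_variable(d, r))) {
        rows[[length(rows) + 1L]] <-
          data.frame(document_id = d$document_id, token = r$token,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(document_id = character(0), token = character(0))
}

.stop_missing <- function(miss) {
  per_doc <- split(miss$token, miss$document_id)
  lines <- vapply(names(per_doc), function(d) {
    sprintf("  %s: %s", d, paste(per_doc[[d]], collapse = ", "))
  }, character(1))
  cond <- structure(
    class = c("nidm_missing_variables", "error", "condition"),
    list(message = paste(c("variable(s) not found in the following document(s):",
                           lines), collapse = "\n"),
         call = NULL, missing = miss))
  stop(cond)
}

#' Pool observations from documents into one rectangular table
#'
#' Resolves each reference in each document, pivots the observations to one
#' row per subject, and stacks rows across documents (each document is a
#' distinct site/dataset: identical subject ids in different documents are
#' different people, never merged). Subjects missing a value for any
#' reference are dropped listwise; the count is reported in the
#' `n_dropped_missing` attribute. Rows are sorted by
#' `(document_id, subject_id)` so observation order in the files is
#' irrelevant.
#'
#' If any reference fails to resolve in any document, an error of class
#' `nidm_missing_variables` is signalled whose message lists the unresolved
#' tokens per document, and no table is produced.
#'
#' @param docs Documents (objects or paths).
#' @param refs Character vector (or list of [variable_ref()]) of distinct
#'   variable references.
#' @return A data frame of class `nidm_table`: columns `document_id`,
#'   `subject_id`, then one column per reference token (numeric, or factor
#'   with the element's declared levels). Attributes: `n_dropped_missing`
#'   (subjects removed for missing values) and `column_info` (per-token value
#'   type, levels, and the element matched in each document).
#' @export
extract_table <- function(docs, refs) {
  docs <- as_nidm_docs(docs)
  if (length(docs) == 0L) stop("no documents given", call. = FALSE)
  refs <- lapply(refs, as_variable_ref)
  if (length(refs) == 0L) stop("no variable references given", call. = FALSE)
  tokens <- vapply(refs, function(r) r$token, character(1))
  if (anyDuplicated(tokens)) {
    stop(sprintf("duplicated variable reference(s): %s",
                 paste(unique(tokens[duplicated(tokens)]), collapse = ", ")),
         call. = FALSE)
  }

  miss <- missing_report(docs, refs)
  if (nrow(miss)) .stop_missing(miss)

  # per-token resolved element in each doc, plus cross-document type agreement
  column_info <- stats::setNames(vector("list", length(tokens)), tokens)
  for (j in seq_along(refs)) {
    els <- lapply(docs, resolve_variable, ref = refs[[j]])
    vts <- unique(vapply(els, function(e) e$value_type, character(1)))
    if (length(vts) > 1L) {
      stop(sprintf("reference '%s' resolves to a numeric element in some documents and a categorical one in others",
                   tokens[j]), call. = FALSE)
    }
    lv <- els[[1]]$levels
    if (vts == "categorical") {
      for (e in els[-1]) {
        if (!setequal(e$levels, lv)) {
          stop(sprintf("reference '%s': documents declare different level sets (%s vs %s)",
                       tokens[j], paste(lv, collapse = ","),
                       paste(e$levels, collapse = ",")), call. = FALSE)
        }
      }
    }
    column_info[[j]] <- list(value_type = vts, levels = lv,
                             elements = vapply(els, function(e) e$element_id,
                                               character(1)))
  }

  n_dropped <- 0L
  blocks <- lapply(docs, function(d) {
    el_ids <- vapply(column_info, function(ci) ci$elements[[d$document_id]],
                     character(1))
    obs <- d$observations[d$observations$element_id %in% el_ids, , drop = FALSE]
    subjects <- sort(unique(obs$subject_id))
    if (length(subjects) == 0L) return(NULL)
    wide <- data.frame(document_id = d$document_id, subject_id = subjects,
                       stringsAsFactors = FALSE)
    for (j in seq_along(tokens)) {
      eid <- column_info[[j]]$elements[[d$document_id]]
      sub <- obs[obs$element_id == eid, , drop = FALSE]
      v <- sub$value[match(subjects, sub$subject_id)]
      wide[[tokens[j]]] <- if (column_info[[j]]$value_type == "numeric") {
        as.numeric(v)
      } else {
        trimws(v)
      }
    }
    keep <- stats::complete.cases(wide)
    n_dropped <<- n_dropped + sum(!keep)
    wide[keep, , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- data.frame(document_id = character(0), subject_id = character(0))
    for (tok in tokens) out[[tok]] <- numeric(0)
  }
  out <- out[order(out$document_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  for (j in seq_along(tokens)) {
    if (column_info[[j]]$value_type == "categorical") {
      out[[tokens[j]]] <- factor(out[[tokens[j]]],
                                 levels = column_info[[j]]$levels)
    }
  }
  structure(out, n_dropped_missing = n_dropped, column_info = column_info,
            class = c("nidm_table", "data.frame"))
}
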