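# NIDM-lite study documents.
#
# A study document describes one dataset or collection site: a set of data
# elements (the data dictionary) plus per-subject observations.  Documents are
# serialized as RDF 1.1 Turtle under the `nlite:` vocabulary:
#
#   @prefix nlite: <urn:nidm-lite:> .
#
#   study node:       a nlite:Study ;        nlite:studyId "<label>"
#   element node:     a nlite:DataElement ;  nlite:elementId "<token>" ;
#                     nlite:sourceVariable "<name>" ; rdfs:label "<text>" ;
#                     nlite:isAbout <conceptURL> (0..n) ;
#                     nlite:valueType "numeric"|"categorical" ;
#                     nlite:levels "<comma-separated>"   (categorical only)
#   observation node: a nlite:Observation ;  nlite:subjectId "<id>" ;
#                     nlite:element <elementNode> ; nlite:value <literal>
#
# Triples outside this profile are ignored (their count is reported via
# message()), so NIDM-lite readers are projections of richer graphs.

NLITE_NS <- "urn:nidm-lite:"

.nl <- function(term) paste0(NLITE_NS, term)
.rdf_type <- function() paste0(TTL_RDF_NS, "type")
.rdfs_label <- function() paste0(TTL_RDFS_NS, "label")

#' Describe one study variable (a data element)
#'
#' A data element is the data-dictionary entry for a study variable: a stable
#' identifier token, the study-local variable name, a human-readable label,
#' zero or more concept URLs annotating what the variable measures (so that
#' semantically equivalent variables can be pooled across sites), and its
#' value type.
#'
#' @param element_id Opaque identifier token, unique within a document
#'   (e.g. `"fs_000008"`).
#' @param source_variable Study-local variable name (e.g. `"DX_GROUP"`).
#' @param label Human-readable description. Defaults to `source_variable`.
#' @param concept_urls Character vector of absolute URLs annotating the
#'   element (may be empty).
#' @param value_type `"numeric"` or `"categorical"`.
#' @param levels Ordered character vector of permitted category labels;
#'   required (non-empty) iff `value_type == "categorical"`. The declared
#'   order fixes the reference level used by contrast codings.
#' @return An object of class `nidm_element`.
#' @examples
#' nidm_element("fs_000008", "brainvol", "supratentorial brain volume",
#'              value_type = "numeric")
#' @export
nidm_element <- function(element_id, source_variable, label = source_variable,
                         concept_urls = character(0),
                         value_type = c("numeric", "categorical"),
                         levels = character(0)) {
  value_type <- match.arg(value_type)
  stopifnot(is.character(element_id), length(element_id) == 1L,
            nzchar(element_id),
            is.character(source_variable), length(source_variable) == 1L,
            nzchar(source_variable))
  levels <- as.character(levels)
  if (value_type == "categorical" && length(levels) == 0L) {
    stop(sprintf("categorical element '%s' must declare its levels", element_id),
         call. = FALSE)
  }
  if (value_type == "numeric" && length(levels) > 0L) {
    stop(sprintf("numeric element '%s' must not declare levels", element_id),
         call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop(sprintf("element '%s' has duplicated levels", element_id), call. = FALSE)
  }
  structure(list(element_id = element_id,
                 source_variable = source_variable,
                 label = label,
                 concept_urls = as.character(concept_urls),
                 value_type = value_type,
                 levels = levels),
            class = "nidm_element")
}

#' Assemble a study document
#'
#' Bundles a site's data elements and per-subject observations. Observations
#' are held as a data frame with columns `subject_id`, `element_id`, `value`;
#' values are kept as character lexical forms and converted according to the
#' element's declared type when a table is extracted.
#'
#' Duplicate `(subject_id, element_id)` observations carrying equal values are
#' collapsed to one (with a message); conflicting duplicates are an error,
#' since silently overwriting them would corrupt downstream regressions.
#'
#' @param document_id Label for the site/dataset.
#' @param elements List of [nidm_element()] objects.
#' @param observations Data frame with character columns `subject_id`,
#'   `element_id`, `value` (zero rows allowed).
#' @return An object of class `nidm_study`.
#' @export
nidm_study <- function(document_id, elements = list(),
                       observations = data.frame(subject_id = character(0),
                                                 element_id = character(0),
                                                 value = character(0))) {
  stopifnot(is.character(document_id), length(document_id) == 1L,
            nzchar(document_id))
  if (inherits(elements, "nidm_element")) elements <- list(elements)
  ids <- vapply(elements, function(e) e$element_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated element_id in document '%s': %s", document_id,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(elements) <- ids
  obs <- data.frame(subject_id = as.character(observations$subject_id),
                    element_id = as.character(observations$element_id),
                    value = as.character(observations$value),
                    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(obs$element_id), ids)
  if (length(unknown)) {
    stop(sprintf("document '%s': observations reference undeclared element(s): %s",
                 document_id, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  key <- paste(obs$subject_id, obs$element_id, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      vals <- unique(obs$value[key == k])
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      if (length(vals) > 1L) {
        stop(sprintf(paste0("document '%s': conflicting duplicate observations for ",
                            "subject '%s', element '%s' (values: %s)"),
                     document_id, parts[1], parts[2],
                     paste(vals, collapse = " vs ")), call. = FALSE)
      }
    }
    message(sprintf("document '%s': collapsed %d duplicate observation(s) with equal values",
                    document_id, sum(duplicated(key))))
    obs <- obs[!duplicated(key), , drop = FALSE]
    rownames(obs) <- NULL
  }
  # type conformance
  for (eid in unique(obs$element_id)) {
    el <- elements[[eid]]
    v <- obs$value[obs$element_id == eid]
    if (el$value_type == "numeric") {
      bad <- v[is.na(suppressWarnings(as.numeric(v)))]
      if (length(bad)) {
        stop(sprintf("document '%s': non-numeric value '%s' for numeric element '%s'",
                     document_id, bad[1], eid), call. = FALSE)
      }
    } else {
      v <- trimws(v)
      bad <- setdiff(unique(v), el$levels)
      if (length(bad)) {
        stop(sprintf("document '%s': value '%s' for element '%s' is not among its levels (%s)",
                     document_id, bad[1], eid, paste(el$levels, collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  structure(list(document_id = document_id, elements = elements,
                 observations = obs),
            class = "nidm_study")
}

#' @export
print.nidm_study <- function(x, ...) {
  cat(sprintf("NIDM-lite study document '%s': %d data element(s), %d observation(s), %d subject(s)\n",
              x$document_id, length(x$elements), nrow(x$observations),
              length(unique(x$observations$subject_id))))
  invisible(x)
}

.node_iri <- function(doc_id, kind, local) {
  paste0(NLITE_NS, "node:", doc_id, ":", kind, ":", local)
}

#' Write a study document as NIDM-lite Turtle
#'
#' Validates the document's invariants, then serializes it as RDF 1.1 Turtle
#' in the NIDM-lite profile. `read_nidm(write_nidm(doc))` reproduces `doc`
#' field by field.
#'
#' @param doc A [nidm_study()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_nidm()]
#' @export
write_nidm <- function(doc, path) {
  if (!inherits(doc, "nidm_study")) stop("`doc` must be a nidm_study", call. = FALSE)
  # re-run invariant validation before any bytes are written
  doc <- nidm_study(doc$document_id, doc$elements, doc$observations)
  q <- function(s) paste0("\"", .ttl_escape(s), "\"")
  lines <- c(
    "@prefix nlite: <urn:nidm-lite:> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    sprintf("<%s> a nlite:Study ;", .node_iri(doc$document_id, "study", "0")),
    sprintf("    nlite:studyId %s .", q(doc$document_id)),
    ""
  )
  for (el in doc$elements) {
    node <- .node_iri(doc$document_id, "element", el$element_id)
    props <- c(
      sprintf("    nlite:elementId %s", q(el$element_id)),
      sprintf("    nlite:sourceVariable %s", q(el$source_variable)),
      sprintf("    rdfs:label %s", q(el$label)),
      vapply(el$concept_urls, function(u) sprintf("    nlite:isAbout <%s>", u),
             character(1), USE.NAMES = FALSE),
      sprintf("    nlite:valueType %s", q(el$value_type)),
      if (el$value_type == "categorical") {
        sprintf("    nlite:levels %s", q(paste(el$levels, collapse = ",")))
      }
    )
    lines <- c(lines, sprintf("<%s> a nlite:DataElement ;", node),
               paste0(props, c(rep(" ;", length(props) - 1L), " .")), "")
  }
  obs <- doc$observations
  if (nrow(obs)) {
    for (r in seq_len(nrow(obs))) {
      node <- .node_iri(doc$document_id, "obs", as.character(r))
      el <- doc$elements[[obs$element_id[r]]]
      val <- if (el$value_type == "numeric") obs$value[r] else q(obs$value[r])
      lines <- c(lines,
                 sprintf("<%s> a nlite:Observation ;", node),
                 sprintf("    nlite:subjectId %s ;", q(obs$subject_id[r])),
                 sprintf("    nlite:element <%s> ;",
                         .node_iri(doc$document_id, "element", obs$element_id[r])),
                 sprintf("    nlite:value %s .", val),
                 "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# all objects for (subject, predicate) in a triple table
.objs <- function(tr, s, p) tr$object[tr$subject == s & tr$predicate == p]

.one_literal <- function(tr, s, p, what, file, required = TRUE) {
  v <- .objs(tr, s, p)
  if (length(v) == 0L) {
    if (!required) return(NA_character_)
    stop(sprintf("%s: node <%s> is missing required property %s", file, s, what),
         call. = FALSE)
  }
  if (length(unique(v)) > 1L) {
    stop(sprintf("%s: node <%s> has multiple values for %s", file, s, what),
         call. = FALSE)
  }
  v[1]
}

#' Read a NIDM-lite Turtle study document
#'
#' Parses an RDF 1.1 Turtle file and projects the NIDM-lite profile out of it:
#' data elements, observations, and the study label. Triples outside the
#' profile are ignored; their count is reported with [message()].
#'
#' @param path Path to a Turtle file.
#' @return A [nidm_study()] object.
#' @seealso [write_nidm()], [list_data_elements()]
#' @export
read_nidm <- function(path) {
  tr <- ttl_parse_file(path)
  used <- rep(FALSE, nrow(tr))
  typ <- .rdf_type()

  study_nodes <- tr$subject[tr$predicate == typ & tr$object == .nl("Study")]
  if (length(unique(study_nodes)) > 1L) {
    stop(sprintf("%s: more than one nlite:Study node", path), call. = FALSE)
  }
  doc_id <- if (length(study_nodes)) {
    .one_literal(tr, study_nodes[1], .nl("studyId"), "nlite:studyId", path)
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }

  el_nodes <- unique(tr$subject[tr$predicate == typ & tr$object == .nl("DataElement")])
  elements <- lapply(el_nodes, function(s) {
    vt <- .one_literal(tr, s, .nl("valueType"), "nlite:valueType", path)
    if (!vt %in% c("numeric", "categorical")) {
      stop(sprintf("%s: element node <%s> has invalid nlite:valueType '%s'",
                   path, s, vt), call. = FALSE)
    }
    lv <- if (vt == "categorical") {
      raw <- .one_literal(tr, s, .nl("levels"), "nlite:levels", path)
      trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    } else character(0)
    nidm_element(
      element_id = .one_literal(tr, s, .nl("elementId"), "nlite:elementId", path),
      source_variable = .one_literal(tr, s, .nl("sourceVariable"),
                                     "nlite:sourceVariable", path),
      label = {
        lb <- .one_literal(tr, s, .rdfs_label(), "rdfs:label", path, required = FALSE)
        if (is.na(lb)) .one_literal(tr, s, .nl("sourceVariable"),
                                    "nlite:sourceVariable", path) else lb
      },
      concept_urls = .objs(tr, s, .nl("isAbout")),
      value_type = vt, levels = lv)
  })
  names(elements) <- vapply(elements, function(e) e$element_id, character(1))
  el_node_to_id <- stats::setNames(names(elements), el_nodes)

  obs_nodes <- unique(tr$subject[tr$predicate == typ & tr$object == .nl("Observation")])
  obs <- if (length(obs_nodes)) {
    do.call(rbind, lapply(obs_nodes, function(s) {
      el_node <- .one_literal(tr, s, .nl("element"), "nlite:element", path)
      if (!el_node %in% names(el_node_to_id)) {
        stop(sprintf("%s: observation <%s> references element node <%s> that is never declared as a nlite:DataElement",
                     path, s, el_node), call. = FALSE)
      }
      data.frame(
        subject_id = .one_literal(tr, s, .nl("subjectId"), "nlite:subjectId", path),
        element_id = el_node_to_id[[el_node]],
        value = .one_literal(tr, s, .nl("value"), "nlite:value", path),
        stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(subject_id = character(0), element_id = character(0),
               value = character(0))
  }

  known_nodes <- c(study_nodes, el_nodes, obs_nodes)
  known_preds <- c(typ, .rdfs_label(),
                   .nl(c("studyId", "elementId", "sourceVariable", "isAbout",
                         "valueType", "levels", "subjectId", "element", "value")))
  in_profile <- tr$subject %in% known_nodes & tr$predicate %in% known_preds
  n_ignored <- sum(!in_profile)
  if (n_ignored > 0L) {
    message(sprintf("%s: ignored %d triple(s) outside the NIDM-lite profile",
                    path, n_ignored))
  }
  nidm_study(doc_id, elements, obs)
}

#' List the data elements available in a set of documents
#'
#' The discovery step before modelling: shows, for every document, each data
#' element's identifier, study-local name, type, levels, and concept
#' annotations, so the user can see what variables are available and how they
#' can be addressed.
#'
#' @param docs A `nidm_study` or list of them (or character paths, which are
#'   read with [read_nidm()]).
#' @return A data frame with one row per (document, element):
#'   `document_id`, `element_id`, `source_variable`, `label`, `value_type`,
#'   `levels` (comma-separated), `concept_urls` (comma-separated).
#' @export
list_data_elements <- function(docs) {
  docs <- as_nidm_docs(docs)
  rows <- lapply(docs, function(d) {
    if (length(d$elements) == 0L) return(NULL)
    do.call(rbind, lapply(d$elements, function(e) {
      data.frame(document_id = d$document_id,
                 element_id = e$element_id,
                 source_variable = e$source_variable,
                 label = e$label,
                 value_type = e$value_type,
                 levels = paste(e$levels, collapse = ","),
                 concept_urls = paste(e$concept_urls, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(document_id = character(0), element_id = character(0),
                      source_variable = character(0), label = character(0),
                      value_type = character(0), levels = character(0),
                      concept_urls = character(0))
  }
  rownames(out) <- NULL
  out
}

# normalize docs argument: nidm_study, list of them, or character paths
as_nidm_docs <- function(docs) {
  if (inherits(docs, "nidm_study")) return(stats::setNames(list(docs), docs$document_id))
  if (is.character(docs)) docs <- lapply(docs, read_nidm)
  if (!is.list(docs) || !all(vapply(docs, inherits, logical(1), "nidm_study"))) {
    stop("`docs` must be nidm_study objects or paths to NIDM-lite Turtle files",
         call. = FALSE)
  }
  stats::setNames(docs, vapply(docs, function(d) d$document_id, character(1)))
}
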