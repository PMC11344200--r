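# Minimal RDF 1.1 Turtle reader/writer.
#
# Scope: the subset the NIDM-lite profile needs — @prefix / PREFIX directives,
# absolute IRIs, prefixed names, blank node labels, the `a` keyword,
# predicate-object lists (';') and object lists (','), string literals with
# escapes and optional datatype/language tag, numeric and boolean literals,
# and '#' comments.  Anonymous blank nodes '[...]' and collections '(...)'
# are rejected with a parse error.  Nothing here is specific to NIDM-lite;
# the profile layer sits on top in documents.R.

TTL_RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
TTL_RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
TTL_XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

# One alternation, longest-match-first where it matters.  Group names are not
# used; classification happens afterwards from the lexeme itself.
.ttl_token_regex <- paste(
  "#[^\\n]*",                                        # comment
  "\"\"\"(?s:.*?)\"\"\"",                            # long string
  "\"(?:[^\"\\\\\\n]|\\\\.)*\"",                     # string
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>",                  # IRI
  "@[A-Za-z]+(?:-[A-Za-z0-9]+)*",                    # directive or lang tag
  "\\^\\^",                                          # datatype marker
  "_:[A-Za-z0-9_][A-Za-z0-9_.-]*",                   # blank node label
  "(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_%.:-]*", # prefixed name (maybe empty local)
  "[+-]?(?:[0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?",  # number
  "[A-Za-z_][A-Za-z0-9_-]*",                         # bare name: a, true, PREFIX...
  "[;,.\\[\\]()]",                                   # punctuation
  sep = "|"
)

# Tokenize Turtle text.  Returns data.frame(text, line); stops on any
# non-whitespace span the lexer cannot account for.
ttl_tokenize <- function(text, file = "<text>") {
  m <- gregexpr(.ttl_token_regex, text, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) {
    starts <- integer(0)
    lens <- integer(0)
  }
  # every character must be inside a token or whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) {
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !(chars %in% c(" ", "\t", "\r", "\n")))
  nl <- c(0L, which(chars == "\n"))
  line_of <- function(pos) findInterval(pos, nl)
  if (length(bad)) {
    stop(sprintf("%s: Turtle parse error near line %d: unexpected character '%s'",
                 file, line_of(bad[1]), chars[bad[1]]), call. = FALSE)
  }
  toks <- substring(text, starts, starts + lens - 1L)
  keep <- !startsWith(toks, "#")
  data.frame(text = toks[keep], line = line_of(starts)[keep],
             stringsAsFactors = FALSE)
}

.ttl_unescape <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  out <- character(0)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      nxt <- chars[i + 1L]
      rep <- switch(nxt,
        "n" = "\n", "t" = "\t", "r" = "\r", "b" = "\b", "f" = "\f",
        "\"" = "\"", "'" = "'", "\\" = "\\",
        "u" = NA_character_, "U" = NA_character_, NULL)
      if (is.null(rep)) {
        stop(sprintf("invalid string escape '\\%s'", nxt), call. = FALSE)
      }
      if (is.na(rep)) {
        width <- if (nxt == "u") 4L else 8L
        hex <- paste(chars[(i + 2L):(i + 1L + width)], collapse = "")
        rep <- intToUtf8(strtoi(hex, 16L))
        i <- i + width
      }
      out <- c(out, rep)
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

.ttl_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

# Parse Turtle text into a triple table:
# data.frame(subject, predicate, object, object_kind ("iri"|"blank"|"literal"),
#            datatype, lang).  Subjects/objects hold absolute IRIs or "_:" labels;
# literal objects hold the unescaped lexical form.
ttl_parse <- function(text, file = "<text>") {
  tk <- ttl_tokenize(text, file)
  prefixes <- character(0)
  subj <- character(0); pred <- character(0); obj <- character(0)
  kind <- character(0); dtype <- character(0); lang <- character(0)
  i <- 1L
  n <- nrow(tk)

  err <- function(msg, at = i) {
    ln <- if (at <= n) tk$line[at] else if (n) tk$line[n] else 0L
    stop(sprintf("%s: Turtle parse error at line %d: %s", file, ln, msg),
         call. = FALSE)
  }
  peek <- function() if (i <= n) tk$text[i] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of input")
    i <<- i + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (!identical(t, what)) err(sprintf("expected '%s', found '%s'", what, t))
    t
  }
  is_iri <- function(t) startsWith(t, "<")
  is_string <- function(t) startsWith(t, "\"")
  is_pname <- function(t) grepl("^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:", t) &&
    !startsWith(t, "_:") && !is_iri(t)
  expand_pname <- function(t) {
    colon <- regexpr(":", t, fixed = TRUE)
    pfx <- substr(t, 1L, colon - 1L)
    local <- substr(t, colon + 1L, nchar(t))
    if (!pfx %in% names(prefixes)) err(sprintf("undeclared prefix '%s:'", pfx), i - 1L)
    paste0(prefixes[[pfx]], local)
  }
  # a prefixed name whose local part ends in '.' has swallowed the statement
  # terminator; put it back
  split_trailing_dot <- function() {
    t <- peek()
    if (!is.na(t) && is_pname(t) && endsWith(t, ".")) {
      tk$text[i] <<- sub("\\.+$", "", t)
      ndots <- nchar(t) - nchar(tk$text[i])
      extra <- data.frame(text = rep(".", ndots), line = tk$line[i])
      tk <<- rbind(tk[seq_len(i), , drop = FALSE], extra,
                   if (i < n) tk[(i + 1L):n, , drop = FALSE])
      n <<- nrow(tk)
    }
  }

  parse_node <- function(role) {
    t <- advance()
    if (is_iri(t)) return(substr(t, 2L, nchar(t) - 1L))
    if (startsWith(t, "_:")) return(t)
    if (t %in% c("[", "(")) err(sprintf("unsupported syntax '%s' (anonymous blank nodes and collections are outside the supported Turtle subset)", t), i - 1L)
    if (is_pname(t)) return(expand_pname(t))
    err(sprintf("expected %s node, found '%s'", role, t), i - 1L)
  }

  parse_object <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of input")
    if (is_string(t)) {
      advance()
      body <- if (startsWith(t, "\"\"\"")) {
        substr(t, 4L, nchar(t) - 3L)
      } else {
        substr(t, 2L, nchar(t) - 1L)
      }
      value <- .ttl_unescape(body)
      dt <- ""
      lg <- ""
      nxt <- peek()
      if (!is.na(nxt) && nxt == "^^") {
        advance()
        dt <- parse_node("datatype")
      } else if (!is.na(nxt) && grepl("^@", nxt) &&
                 !nxt %in% c("@prefix", "@base")) {
        advance()
        lg <- substr(nxt, 2L, nchar(nxt))
      }
      return(list(o = value, kind = "literal", dtype = dt, lang = lg))
    }
    if (grepl("^[+-]?[0-9.]", t) && grepl("[0-9]", t)) {
      advance()
      dt <- if (grepl("[eE]", t)) paste0(TTL_XSD_NS, "double")
      else if (grepl(".", t, fixed = TRUE)) paste0(TTL_XSD_NS, "decimal")
      else paste0(TTL_XSD_NS, "integer")
      return(list(o = t, kind = "literal", dtype = dt, lang = ""))
    }
    if (t %in% c("true", "false")) {
      advance()
      return(list(o = t, kind = "literal",
                  dtype = paste0(TTL_XSD_NS, "boolean"), lang = ""))
    }
    node <- parse_node("object")
    list(o = node, kind = if (startsWith(node, "_:")) "blank" else "iri",
         dtype = "", lang = "")
  }

  emit <- function(s, p, ob) {
    subj <<- c(subj, s); pred <<- c(pred, p); obj <<- c(obj, ob$o)
    kind <<- c(kind, ob$kind); dtype <<- c(dtype, ob$dtype); lang <<- c(lang, ob$lang)
  }

  while (i <= n) {
    t <- peek()
    if (t %in% c("@prefix", "PREFIX", "prefix")) {
      sparql_style <- t != "@prefix"
      advance()
      pname <- advance()
      if (!is_pname(pname) || !endsWith(pname, ":")) {
        err(sprintf("expected 'prefix:' after %s, found '%s'", t, pname), i - 1L)
      }
      iri_tok <- advance()
      if (!is_iri(iri_tok)) err("expected IRI in prefix declaration", i - 1L)
      prefixes[[substr(pname, 1L, nchar(pname) - 1L)]] <-
        substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (!sparql_style) expect(".")
      next
    }
    if (t %in% c("@base", "BASE", "base")) {
      err("@base / relative IRIs are outside the supported Turtle subset")
    }
    s <- parse_node("subject")
    repeat {
      split_trailing_dot()
      ptok <- peek()
      p <- if (identical(ptok, "a")) {
        advance()
        paste0(TTL_RDF_NS, "type")
      } else {
        parse_node("predicate")
      }
      repeat {
        split_trailing_dot()
        emit(s, p, parse_object())
        split_trailing_dot()
        if (identical(peek(), ",")) advance() else break
      }
      sep <- advance()
      if (sep == ";") {
        # tolerate ';' immediately before '.'
        split_trailing_dot()
        if (identical(peek(), ".")) { advance(); break }
        next
      }
      if (sep == ".") break
      err(sprintf("expected ';' or '.', found '%s'", sep), i - 1L)
    }
  }

  data.frame(subject = subj, predicate = pred, object = obj,
             object_kind = kind, datatype = dtype, lang = lang,
             stringsAsFactors = FALSE)
}

ttl_parse_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ttl_parse(paste(readLines(path, warn = FALSE), collapse = "\n"),
            file = path)
}
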