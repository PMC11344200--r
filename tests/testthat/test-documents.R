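# NIDM-lite document reading, writing, and element listing.

test_that("a written document is read back field-by-field", {
  doc <- tiny_study()
  path <- withr::local_tempfile(fileext = ".ttl")
  write_nidm(doc, path)
  expect_identical(read_nidm(path), doc)
})

test_that("an empty document writes to prefixes only and reads back empty", {
  doc <- nidm_study("empty")
  path <- withr::local_tempfile(fileext = ".ttl")
  write_nidm(doc, path)
  body <- readLines(path)
  expect_true(all(grepl("^@prefix|^<|^\\s*$|nlite:studyId", body)))
  back <- read_nidm(path)
  expect_length(back$elements, 0)
  expect_identical(nrow(back$observations), 0L)
})

test_that("valid Turtle with zero NIDM-lite triples parses to an empty document", {
  path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix ex: <http://example.org/> .",
    "ex:thing a ex:Widget ;",
    "    ex:label \"nothing to see\" ."), path)
  doc <- suppressMessages(read_nidm(path))
  expect_length(doc$elements, 0)
  expect_identical(nrow(doc$observations), 0L)
})

test_that("triples outside the profile never change the parsed document", {
  doc <- tiny_study()
  path <- withr::local_tempfile(fileext = ".ttl")
  write_nidm(doc, path)
  extra <- c("",
             "@prefix prov: <http://www.w3.org/ns/prov#> .",
             "<urn:x:act1> a prov:Activity ;",
             "    prov:wasAssociatedWith <urn:x:agent1> , <urn:x:agent2> ;",
             "    prov:label \"extra provenance, with escapes \\\"quoted\\\"\"@en .")
  cat(paste(extra, collapse = "\n"), "\n", file = path, append = TRUE)
  expect_identical(suppressMessages(read_nidm(path)), doc)
})

test_that("unparseable Turtle and undeclared elements give named errors", {
  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix nlite: <urn:nidm-lite:> .",
               "<urn:x> nlite:value %%% ."), bad)
  expect_error(read_nidm(bad), "parse error.*line 2")

  orphan <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix nlite: <urn:nidm-lite:> .",
    "<urn:obs1> a nlite:Observation ;",
    "    nlite:subjectId \"s1\" ;",
    "    nlite:element <urn:ghost> ;",
    "    nlite:value 3.5 ."), orphan)
  expect_error(read_nidm(orphan), "urn:ghost.*never declared")
})

test_that("duplicate observations collapse when equal and error when conflicting", {
  el <- nidm_element("e1", "x", value_type = "numeric")
  obs_eq <- data.frame(subject_id = c("s1", "s1"), element_id = "e1",
                       value = c("3", "3"))
  expect_message(doc <- nidm_study("d", list(el), obs_eq), "duplicate")
  expect_identical(nrow(doc$observations), 1L)
  obs_conflict <- data.frame(subject_id = c("s1", "s1"), element_id = "e1",
                             value = c("3", "4"))
  expect_error(nidm_study("d", list(el), obs_conflict),
               "conflicting duplicate.*'s1'.*'e1'")
})

test_that("categorical invariants are enforced", {
  expect_error(nidm_element("e", "x", value_type = "categorical"),
               "must declare its levels")
  el <- nidm_element("e", "x", value_type = "categorical", levels = c("a", "b"))
  expect_error(
    nidm_study("d", list(el),
               data.frame(subject_id = "s1", element_id = "e", value = "z")),
    "not among its levels")
})

test_that("categorical levels survive serialization in declared order", {
  el <- nidm_element("e", "grp", value_type = "categorical",
                     levels = c("ctrl", "mild", "severe"))
  path <- withr::local_tempfile(fileext = ".ttl")
  write_nidm(nidm_study("d", list(el)), path)
  expect_identical(read_nidm(path)$elements[["e"]]$levels,
                   c("ctrl", "mild", "severe"))
})

test_that("list_data_elements enumerates every element of every document", {
  d1 <- tiny_study("one")
  d2 <- nidm_study("two", list(
    nidm_element("a1", "x", value_type = "numeric"),
    nidm_element("a2", "y", value_type = "numeric")))
  listing <- list_data_elements(list(d1, d2))
  expect_identical(nrow(listing), 5L)
  expect_setequal(unique(listing$document_id), c("one", "two"))
  expect_true("http://uri.interlex.org/ilx_0100400" %in% listing$concept_urls)
  empty <- list_data_elements(list())
  expect_identical(nrow(empty), 0L)
})

test_that("an independent RDF parser agrees on the triple content", {
  py <- Sys.which("python")
  doc <- tiny_study()
  path <- withr::local_tempfile(fileext = ".ttl")
  write_nidm(doc, path)
  count <- system2(py, c("-c", shQuote(paste0(
    "import rdflib,sys; g=rdflib.Graph(); g.parse(sys.argv[1], format='turtle'); print(len(g))"
  )), path), stdout = TRUE)
  # study: type+id; numeric element: type,id,source,label,valueType;
  # categorical adds levels; concept adds isAbout; observation: 4 triples
  expected <- 2L + (5L + 1L) + (5L + 1L) + 5L + 9L * 4L
  expect_identical(as.integer(count), expected)

  # re-serialize with rdflib (different layout/quoting) and read it back
  reser <- withr::local_tempfile(fileext = ".ttl")
  system2(py, c("-c", shQuote(paste0(
    "import rdflib,sys; g=rdflib.Graph(); g.parse(sys.argv[1], format='turtle');",
    "g.serialize(destination=sys.argv[2], format='turtle')"
  )), path, reser))
  back <- read_nidm(reser)
  expect_identical(back$elements[sort(names(back$elements))],
                   doc$elements[sort(names(doc$elements))])
  o1 <- doc$observations[order(doc$observations$subject_id,
                               doc$observations$element_id), ]
  o2 <- back$observations[order(back$observations$subject_id,
                                back$observations$element_id), ]
  expect_identical(o1$subject_id, o2$subject_id)
  expect_identical(o1$element_id, o2$element_id)
  expect_equal(as.numeric(o1$value), as.numeric(o2$value))
})
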