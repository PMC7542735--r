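tax <- build_taxonomy()
scenarios <- lapply(1:3, build_scenario)

test_that("taxonomy and stores round-trip through every supported format", {
  for (fmt in c("json", "ttl", "ofn")) {
    doc <- export_taxonomy(tax, fmt)
    expect_true(taxonomy_equal(tax, import_document(doc)),
                label = sprintf("taxonomy %s round trip", fmt))
    for (i in 1:3) {
      sdoc <- export_store(scenarios[[i]], fmt)
      expect_true(rt_equal(scenarios[[i]], import_document(sdoc)),
                  label = sprintf("scenario %d %s round trip", i, fmt))
    }
  }
})

test_that("export is byte-deterministic", {
  for (fmt in c("json", "ttl", "ofn")) {
    expect_identical(export_taxonomy(tax, fmt)$content,
                     export_taxonomy(build_taxonomy(), fmt)$content)
    expect_identical(export_store(scenarios[[2]], fmt)$content,
                     export_store(build_scenario(2), fmt)$content)
  }
})

test_that("the symbiosis equivalence axiom carries the min-2 participant restriction", {
  ttl <- paste(export_taxonomy(tax, "ttl")$content, collapse = "\n")
  expect_match(ttl, "owl:minQualifiedCardinality \"2\"", fixed = TRUE)
  expect_match(ttl, "symb:has-participant", fixed = TRUE)
  expect_match(ttl, "obo:GO_0051705", fixed = TRUE)  # multi-organism behavior
  expect_match(ttl, "symb:spatially-disjoint-from", fixed = TRUE)
  expect_match(ttl, "symb:located-in", fixed = TRUE)
  ofn <- paste(export_taxonomy(tax, "ofn")$content, collapse = "\n")
  expect_match(ofn, "ObjectMinCardinality(2 symb:has-participant", fixed = TRUE)
})

test_that("imported classes are emitted as references only", {
  ttl <- export_taxonomy(tax, "ttl")$content
  go_lines <- grep("^obo:GO_", ttl, value = TRUE)
  expect_length(go_lines, 3L)
  expect_false(any(grepl("IAO_0000115", go_lines)))  # no definition annotation
  expect_false(any(grepl("symb:differentia", go_lines)))
})

test_that("an empty store exports to a prefix-only document", {
  doc <- export_store(rt_store(), "ttl")
  body <- doc$content[!startsWith(doc$content, "@prefix") &
                        nzchar(doc$content)]
  expect_equal(body, "symb:t_max a symb:TemporalRegion .")
  expect_true(rt_equal(rt_store(), import_document(doc)))
})

test_that("scenario exports carry their printed statements", {
  s3ttl <- export_store(scenarios[[3]], "ttl")$content
  hit <- grepl("rdf:subject symb:IUI-15", s3ttl) &
    grepl("rdf:predicate symb:precedes", s3ttl) &
    grepl("rdf:object symb:IUI-16", s3ttl)
  expect_equal(sum(hit), 1L)
  s2 <- import_document(export_store(scenarios[[2]], "json"))
  expect_equal(nrow(s2$relations), 19L)
})

test_that("malformed documents raise parse errors with context", {
  expect_error(import_document(""), class = "symbio_parse_error")
  expect_error(import_document("not a document"),
               class = "symbio_parse_error")
  ofn <- export_store(scenarios[[1]], "ofn")$content
  truncated <- ofn[-length(ofn)]  # drop the closing ")"
  expect_error(import_document(truncated), class = "symbio_parse_error")
  expect_error(import_document('{"kind": "mystery"}'),
               class = "symbio_parse_error")
  expect_error(export_taxonomy(tax, "xml"), class = "symbio_format_error")
  expect_error(export_store(scenarios[[1]], "rdfxml"),
               class = "symbio_format_error")
})

test_that("documents survive the file system", {
  path <- withr::local_tempfile(fileext = ".ttl")
  write_document(export_store(scenarios[[1]], "ttl"), path)
  expect_true(rt_equal(scenarios[[1]], import_document(path)))
})

test_that("the emitted Turtle is syntactically valid for an independent RDF parser", {
  python <- Sys.which("python")
  expect_true(nzchar(python))
  dir <- withr::local_tempdir()
  tax_path <- file.path(dir, "tax.ttl")
  store_path <- file.path(dir, "store.ttl")
  write_document(export_taxonomy(tax, "ttl"), tax_path)
  write_document(export_store(scenarios[[2]], "ttl"), store_path)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, rdflib",
    "for f in sys.argv[1:]:",
    "    g = rdflib.Graph()",
    "    g.parse(f, format='turtle')",
    "    print(len(g))"
  ), script)
  out <- suppressWarnings(
    system2(python, c(script, tax_path, store_path), stdout = TRUE))
  expect_null(attr(out, "status"))
  expect_length(out, 2L)
  expect_true(all(as.integer(out) > 0L))
})
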