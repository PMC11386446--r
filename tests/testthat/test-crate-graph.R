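test_that("reading preserves literals and references exactly", {
  cr <- read_crate(annotation_snippet_json())
  f <- resolve(cr, "final-annotations.tsv")
  expect_identical(first_literal(f, "contentSize"), "14784")
  expect_identical(prop_ids(f, "exampleOfWork"), "#annotations")
  p <- resolve(cr, "#annotations")
  expect_identical(first_literal(p, "additionalType"), "File")
  expect_identical(first_literal(p, "valueRequired"), "True")
  expect_null(resolve(cr, "#no-such-entity"))
  expect_identical(resolve(cr, crate_root(cr)$id)$id, "./")
})

test_that("a minimal crate has only descriptor and root", {
  txt <- '{"@context": "https://w3id.org/ro/crate/1.1/context", "@graph": [
    {"@id": "ro-crate-metadata.json", "@type": "CreativeWork",
     "about": {"@id": "./"}},
    {"@id": "./", "@type": "Dataset"}]}'
  cr <- read_crate(txt)
  expect_length(crate_ids(cr), 2L)
  expect_identical(crate_descriptor(cr)$id, "ro-crate-metadata.json")
})

test_that("malformed documents raise structural errors", {
  expect_error(read_crate('{"@context": "x"}'), "no @graph")
  expect_error(read_crate('{"@graph": []}'), "no @context")
  no_root <- '{"@context": "c", "@graph": [
    {"@id": "ro-crate-metadata.json", "@type": "CreativeWork",
     "about": {"@id": "./"}}]}'
  expect_error(read_crate(no_root), "missing root dataset")
  no_desc <- '{"@context": "c", "@graph": [{"@id": "./", "@type": "Dataset"}]}'
  expect_error(read_crate(no_desc), "missing metadata descriptor")
  dup <- '{"@context": "c", "@graph": [
    {"@id": "ro-crate-metadata.json", "@type": "CreativeWork",
     "about": {"@id": "./"}},
    {"@id": "./", "@type": "Dataset"}, {"@id": "./", "@type": "Dataset"}]}'
  expect_error(read_crate(dup), "duplicate @id")
  untyped <- '{"@context": "c", "@graph": [{"@id": "x"}]}'
  expect_error(read_crate(untyped), "no @type")
})

test_that("write/read round-trips every fixture and writes are deterministic", {
  for (name in c("head-sort", "annotation", "pathology", "cpm")) {
    cr <- fresh_fixture(name)
    txt <- write_crate(cr)
    expect_identical(txt, write_crate(cr), info = name)
    cr2 <- read_crate(txt)
    expect_true(crate_equal(cr, cr2), info = name)
    expect_identical(txt, write_crate(cr2), info = name)
  }
})

test_that("round trip is insensitive to key order in the input document", {
  scrambled <- '{"@context": "https://w3id.org/ro/crate/1.1/context", "@graph": [
    {"@id": "final-annotations.tsv", "exampleOfWork": {"@id": "#annotations"},
     "contentSize": "14784", "@type": "File"},
    {"about": {"@id": "./"}, "@type": "CreativeWork",
     "@id": "ro-crate-metadata.json"},
    {"@type": "Dataset", "@id": "./"},
    {"name": "annotations", "@type": "FormalParameter", "@id": "#annotations"}]}'
  a <- read_crate(scrambled)
  b <- read_crate(write_crate(a))
  expect_true(crate_equal(a, b))
})

test_that("type filtering matches hand-enumerated fixture contents", {
  path <- fresh_fixture("pathology")
  expect_length(entities_of_type(path, "CreateAction"), 4L)
  # 9 workflow inputs + 2 workflow outputs + 2 tools x (5 inputs + 1 output)
  expect_length(entities_of_type(path, "FormalParameter"), 23L)
  expect_length(entities_of_type(fresh_fixture("head-sort"), "OrganizeAction"),
                0L)
})

test_that("dangling references are only external profile/spec URIs", {
  for (name in c("head-sort", "annotation", "pathology", "cpm")) {
    d <- dangling_refs(fresh_fixture(name))
    expect_true(all(d$external), info = name)
  }
  cr <- new_crate()
  crate_append_prop(cr, "./", "hasPart", ref("missing.txt"))
  d <- dangling_refs(cr)
  expect_identical(d$to[!d$external], "missing.txt")
})

test_that("property normalization is idempotent and ids are checked", {
  p <- normalize_props(list(a = "x", b = list("y", ref("#z")), c = 3))
  expect_identical(normalize_props(p), p)
  expect_identical(p$a, list("x"))
  expect_error(entity("bad id", "File"), "whitespace")
  expect_error(entity("", "File"), "non-empty")
  expect_error(entity("x", character()), "at least one type")
})
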