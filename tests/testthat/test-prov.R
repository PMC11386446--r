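prov_pred <- function(prov, term) {
  prov[prov$predicate == paste0("http://www.w3.org/ns/prov#", term), ,
       drop = FALSE]
}

# expected edge counts, recomputed from the crate's own lists: activities
# cannot be `used` or generate in PROV, so action-typed members are excluded
expected_counts <- function(cr) {
  actions <- c(entities_of_type(cr, "CreateAction"),
               entities_of_type(cr, "OrganizeAction"))
  is_action <- function(id) {
    e <- resolve(cr, id)
    !is.null(e) && any(c("CreateAction", "ControlAction", "OrganizeAction")
                       %in% e$types)
  }
  used <- sum(vapply(actions, function(a)
    sum(!vapply(prop_ids(a, "object"), is_action, logical(1))), numeric(1)))
  gen <- sum(vapply(actions, function(a)
    sum(!vapply(prop_ids(a, "result"), is_action, logical(1))), numeric(1)))
  c(used = used, generated = gen)
}

test_that("used/wasGeneratedBy counts conserve object/result list lengths", {
  for (name in c("head-sort", "annotation", "pathology", "cpm")) {
    cr <- fresh_fixture(name)
    p <- to_prov(cr)
    want <- expected_counts(cr)
    expect_identical(nrow(prov_pred(p, "used")), as.integer(want[["used"]]),
                     info = name)
    expect_identical(nrow(prov_pred(p, "wasGeneratedBy")),
                     as.integer(want[["generated"]]), info = name)
  }
})

test_that("action-to-action links are omitted with an annotation", {
  cr <- fresh_fixture("pathology")
  p <- to_prov(cr)
  control_iris <- paste0("arcp://wrroc/",
                         utils::URLencode(paste0("#control-000", 1:3)))
  expect_false(any(prov_pred(p, "used")$object %in% control_iris))
  expect_true(any(grepl("omitted action-to-action",
                        attr(p, "annotations"))))
})

test_that("agents yield associations with a plan; absent agents yield none", {
  cr <- fresh_fixture("pathology")
  p <- to_prov(cr)
  qa <- prov_pred(p, "qualifiedAssociation")
  # only the workflow-level run has an agent
  expect_identical(nrow(qa), 1L)
  expect_match(qa$subject, "30a65cba")
  hp <- prov_pred(p, "hadPlan")
  expect_identical(nrow(hp), 1L)
  expect_match(hp$object, "predictions.cwl")
  expect_identical(nrow(prov_pred(p, "wasAssociatedWith")), 1L)

  # Person typing from the exact-match rows
  wa <- prov_pred(p, "wasAssociatedWith")
  expect_true(any(p$object == "http://www.w3.org/ns/prov#Person" &
                    p$subject == wa$object))

  no_agent <- fresh_fixture("cpm")
  p2 <- to_prov(no_agent)
  expect_identical(nrow(prov_pred(p2, "qualifiedAssociation")), 0L)
})

test_that("plans are typed both Plan and Entity; values are Entities", {
  p <- to_prov(fresh_fixture("pathology"))
  wf_iri <- "arcp://wrroc/predictions.cwl"
  types <- p$object[p$subject == wf_iri &
                      p$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"]
  expect_true(all(paste0("http://www.w3.org/ns/prov#", c("Plan", "Entity"))
                  %in% types))
  pv_iri <- paste0("arcp://wrroc/", utils::URLencode("#tissue-low-level-pv"))
  expect_true(any(p$subject == pv_iri &
                    p$object == "http://www.w3.org/ns/prov#Entity"))
})

test_that("timestamps export as typed dateTime literals when parseable", {
  p <- to_prov(fresh_fixture("pathology"))
  st <- prov_pred(p, "startedAtTime")
  expect_identical(nrow(st), 4L)  # the four runs; the engine run has no time
  expect_true(all(st$kind == "literal"))
  expect_true(all(st$datatype == "http://www.w3.org/2001/XMLSchema#dateTime"))
})

test_that("export is deterministic and refuses non-conformant crates", {
  cr <- fresh_fixture("head-sort")
  expect_identical(as_ntriples(to_prov(cr)),
                   as_ntriples(to_prov(fresh_fixture("head-sort"))))
  expect_error(to_prov(new_crate()), "does not conform")
})

test_that("serializations are well-formed line formats", {
  p <- to_prov(fresh_fixture("head-sort"))
  nt <- strsplit(as_ntriples(p), "\n")[[1]]
  expect_length(nt, nrow(p))
  expect_true(all(grepl("^<[^ ]+> <[^ ]+> .+ \\.$", nt)))
  pn <- as_provn(p)
  expect_match(pn, "^document\n")
  expect_match(pn, "endDocument$")
})

test_that("the term mapping answers lookups and flags unexported rows", {
  m <- lookup_mapping("object")
  expect_identical(m$relation, "exact")
  expect_identical(m$prov, "used")
  expect_identical(nrow(lookup_mapping("alternateName")), 0L)
  rel <- mapping_table()
  expect_false(any(rel$exported[rel$relation == "related" &
                                  rel$term != "instrument"]))
  p <- to_prov(fresh_fixture("pathology"))
  expect_true(any(grepl("related-match mapping not exported",
                        attr(p, "annotations"))))
})

test_that("every applicable mapped term is realized in the pathology export", {
  cr <- fresh_fixture("pathology")
  p <- to_prov(cr)
  crate_has_term <- function(term) {
    if (term == "agent+instrument") term <- "agent"
    any(vapply(cr$graph, function(e)
      term %in% e$types || term %in% names(e$props), logical(1)))
  }
  statements_mention <- function(prov_terms) {
    any(vapply(prov_terms, function(t) {
      iri <- paste0("http://www.w3.org/ns/prov#", t)
      any(p$predicate == iri | p$object == iri)
    }, logical(1)))
  }
  m <- mapping_table()
  for (i in seq_len(nrow(m))) {
    if (!m$exported[i] || !crate_has_term(m$term[i])) next
    terms <- trimws(strsplit(m$prov[i], ",")[[1]])
    terms <- sub(" on Association", "", terms)
    expect_true(statements_mention(terms), info = m$term[i])
  }
})
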