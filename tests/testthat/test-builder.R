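process_scaffold <- function() {
  cr <- new_crate(name = "t", deterministic_ids = TRUE)
  add_data_entity(cr, "#tool", "SoftwareApplication", name = "tool",
                  in_root = FALSE)
  add_data_entity(cr, "in.txt", "File")
  add_data_entity(cr, "out.txt", "File")
  cr
}

test_that("run specs enforce status/error and time ordering", {
  expect_error(run_spec("#t", status = "Completed", error = "boom"),
               "only be set when status is Failed")
  expect_error(run_spec("#t", start = "2024-01-02T00:00:00+00:00",
                        end = "2024-01-01T00:00:00+00:00"), "after end")
  s <- run_spec("#t", status = "Failed", error = "boom")
  expect_identical(s$error, "boom")
})

test_that("process runs require a software-typed instrument", {
  cr <- process_scaffold()
  expect_error(add_process_run(cr, run_spec("#nope")), "not in crate")
  add_data_entity(cr, "#person", "Person", in_root = FALSE)
  expect_error(add_process_run(cr, run_spec("#person")),
               "SoftwareApplication")
  id <- add_process_run(cr, run_spec("#tool", inputs = "in.txt",
                                     outputs = "out.txt"))
  a <- resolve(cr, id)
  expect_identical(prop_ids(a, "object"), "in.txt")
  expect_true(id %in% prop_ids(crate_root(cr), "mentions"))
  bare <- add_process_run(cr, run_spec("#tool"))
  expect_length(prop_values(resolve(cr, bare), "object"), 0L)
  expect_length(prop_values(resolve(cr, bare), "result"), 0L)
})

test_that("non-file values get deterministic, collision-free ids", {
  cr <- process_scaffold()
  a <- add_non_file_value(cr, "tissue-low-level", "9")
  expect_identical(a, "#tissue-low-level-pv")
  b <- add_non_file_value(cr, "tissue-low-level", "10")
  expect_false(identical(a, b))
  expect_identical(first_literal(resolve(cr, b), "value"), "10")
  expect_error(add_non_file_value(cr, "", "x"), "non-empty")
})

test_that("only one main workflow is allowed", {
  cr <- new_crate(deterministic_ids = TRUE)
  wf <- add_workflow(cr, "wf.cwl", language_hint = "cwl")
  e <- resolve(cr, wf)
  expect_setequal(e$types, c("File", "SoftwareSourceCode",
                             "ComputationalWorkflow"))
  expect_identical(prop_ids(crate_root(cr), "mainEntity"), "wf.cwl")
  expect_error(add_workflow(cr, "wf2.cwl"), "already has a main workflow")
})

test_that("formal parameters are owned, unique and typed", {
  cr <- new_crate(deterministic_ids = TRUE)
  wf <- add_workflow(cr, "wf.cwl")
  pid <- add_formal_parameter(cr, wf, "input", param_spec(
    "#annotations", "annotations", additional_type = "File",
    encoding_format = "text/tab-separated-values", value_required = TRUE))
  p <- resolve(cr, pid)
  expect_identical(first_literal(p, "encodingFormat"),
                   "text/tab-separated-values")
  expect_identical(first_literal(p, "valueRequired"), "True")
  expect_identical(prop_ids(resolve(cr, wf), "input"), pid)
  expect_error(add_formal_parameter(cr, wf, "input", param_spec(
    "#annotations", "annotations")), "duplicate parameter id")
  expect_error(add_formal_parameter(cr, "#missing", "input", param_spec(
    "#p2", "p2")), "not in crate")
})

test_that("realization links accumulate and are type-checked", {
  cr <- new_crate(deterministic_ids = TRUE)
  wf <- add_workflow(cr, "wf.cwl")
  p1 <- add_formal_parameter(cr, wf, "input", param_spec("#p1", "p1"))
  add_data_entity(cr, "tool.cwl", c("SoftwareApplication", "File"))
  p2 <- add_formal_parameter(cr, "tool.cwl", "input",
                             param_spec("tool.cwl#src", "src"))
  add_data_entity(cr, "x.dat", "File")
  link_realization(cr, "x.dat", p1)
  link_realization(cr, "x.dat", p2)
  expect_identical(prop_ids(resolve(cr, "x.dat"), "exampleOfWork"),
                   c(p1, p2))
  expect_error(link_realization(cr, "x.dat", "tool.cwl"),
               "not a FormalParameter")
  expect_error(link_realization(cr, p1, p1), "realize itself")
})

test_that("steps share hasPart entries and reject position collisions", {
  cr <- fresh_fixture("pathology")
  wf <- resolve(cr, "predictions.cwl")
  expect_length(prop_ids(wf, "step"), 3L)
  expect_setequal(intersect(prop_ids(wf, "hasPart"),
                            c("extract_tissue.cwl", "classify_tumor.cwl")),
                  c("extract_tissue.cwl", "classify_tumor.cwl"))
  expect_identical(prop_ids(resolve(cr, "predictions.cwl#extract-tissue-low"),
                            "workExample"), "extract_tissue.cwl")
  expect_error(add_step(cr, "predictions.cwl", "extract_tissue.cwl", 0,
                        "again"), "position 0 already used")
  expect_error(add_step(cr, "predictions.cwl", "#operator", 5, "bad"),
               "SoftwareApplication")
})

test_that("step executions point at steps and actions only", {
  cr <- fresh_fixture("pathology")
  expect_error(add_step_execution(cr, "predictions.cwl#extract-tissue-low",
                                  character()), "at least one action")
  expect_error(add_step_execution(cr, "extract_tissue.cwl", "#control-0001"),
               "not a HowToStep")
  expect_error(add_step_execution(cr, "predictions.cwl#extract-tissue-low",
                                  "streamflow.yml"), "not a CreateAction")
  # scatter: one step controlling two executions of the same tool
  id <- add_step_execution(cr, "predictions.cwl#extract-tissue-low",
                           c("#457c80d0-75e8-46d6-bada-b3fe82ea0ef1",
                             "#d09a8355-1a14-4ea4-b00b-122e010e5cc9"))
  expect_length(prop_ids(resolve(cr, id), "object"), 2L)
})

test_that("engine runs aggregate step executions, config and result", {
  cr <- fresh_fixture("pathology")
  oa <- resolve(cr, "#organize-0001")
  expect_identical(prop_ids(oa, "instrument"), "#streamflow")
  expect_true("streamflow.yml" %in% prop_ids(oa, "object"))
  res <- prop_ids(oa, "result")
  expect_identical(prop_ids(resolve(cr, res), "instrument"),
                   "predictions.cwl")
  expect_error(add_engine_run(cr, "#streamflow", "#control-0001",
                              "streamflow.yml"), "workflow-level CreateAction")
  bare <- add_engine_run(cr, "#streamflow", "#control-0001",
                         "#30a65cba-1b75-47dc-ad47-1d33819cf156")
  expect_identical(prop_ids(resolve(cr, bare), "object"), "#control-0001")
})

test_that("parameter connections are held by steps or the workflow", {
  cr <- fresh_fixture("pathology")
  expect_error(add_parameter_connection(
    cr, "predictions.cwl#extract-tissue-low",
    "predictions.cwl#slide", "predictions.cwl#slide"), "must differ")
  expect_error(add_parameter_connection(
    cr, "extract_tissue.cwl",
    "predictions.cwl#slide", "extract_tissue.cwl#src"),
    "HowToStep or the main workflow")
  expect_error(add_parameter_connection(
    cr, "predictions.cwl#extract-tissue-low",
    "predictions.cwl#slide", "streamflow.yml"), "not a FormalParameter")
})

test_that("collections validate parts and main entity", {
  cr <- process_scaffold()
  expect_error(add_collection(cr, character()), "at least one part")
  expect_error(add_collection(cr, "in.txt", main = "out.txt"),
               "one of the parts")
  single <- add_collection(cr, "in.txt", main = "in.txt")
  expect_identical(prop_ids(resolve(cr, single), "mainEntity"), "in.txt")
})

test_that("alternate names overwrite rather than accumulate", {
  cr <- process_scaffold()
  set_alternate_name(cr, "in.txt", "first.txt")
  set_alternate_name(cr, "in.txt", "second.txt")
  expect_identical(prop_values(resolve(cr, "in.txt"), "alternateName"),
                   list("second.txt"))
})

test_that("builder output is reproducible under deterministic ids", {
  for (name in c("head-sort", "annotation", "pathology", "cpm"))
    expect_identical(write_crate(fresh_fixture(name)),
                     write_crate(fresh_fixture(name)), info = name)
})

test_that("every builder step preserves crate structural invariants", {
  cr <- new_crate(name = "incremental", deterministic_ids = TRUE)
  check <- function() {
    expect_identical(prop_ids(crate_descriptor(cr), "about"),
                     crate_root(cr)$id)
    expect_true(all(dangling_refs(cr)$external))
    cr2 <- read_crate(write_crate(cr))
    expect_true(crate_equal(cr, cr2))
  }
  add_data_entity(cr, "#tool", "SoftwareApplication", in_root = FALSE); check()
  add_data_entity(cr, "a.txt", "File"); check()
  wf <- add_workflow(cr, "wf.cwl", language_hint = "cwl"); check()
  p <- add_formal_parameter(cr, wf, "input", param_spec("#in", "in")); check()
  link_realization(cr, "a.txt", p); check()
  run <- add_process_run(cr, run_spec(wf, inputs = "a.txt")); check()
  st <- add_step(cr, wf, "#tool", 0); check()
  ca <- add_step_execution(cr, st, run); check()
  add_engine_run(cr, "#tool", ca, run); check()
})
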