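test_that("the pathology run report reproduces the recorded listing", {
  rep <- action_report(fresh_fixture("pathology"))
  expect_length(rep, 4L)
  expect_identical(render_report(rep), pathology_report_golden())
})

test_that("the training-pipeline report reproduces the recorded structure", {
  rep <- action_report(fresh_fixture("cpm"))
  expect_length(rep, 7L)
  expect_identical(report_structure_lines(render_report(rep)),
                   cpm_report_structure_golden())
})

test_that("the report is a pure function of the document bytes", {
  txt <- write_crate(fresh_fixture("pathology"))
  r1 <- render_report(action_report(read_crate(txt)))
  r2 <- render_report(action_report(read_crate(txt)))
  expect_identical(r1, r2)
})

test_that("reported value/parameter pairs mirror exampleOfWork edges", {
  cr <- fresh_fixture("pathology")
  for (s in action_report(cr)) {
    owned_in <- prop_ids(resolve(cr, s$instrument), "input")
    owned_out <- prop_ids(resolve(cr, s$instrument), "output")
    for (v in s$inputs) {
      if (is.na(v$parameter)) next
      expect_true(v$parameter %in%
                    prop_ids(resolve(cr, v$entity), "exampleOfWork"))
      expect_true(v$parameter %in% owned_in)
    }
    for (v in s$outputs) {
      if (is.na(v$parameter)) next
      expect_true(v$parameter %in%
                    prop_ids(resolve(cr, v$entity), "exampleOfWork"))
      expect_true(v$parameter %in% owned_out)
    }
  }
})

test_that("values realizing only foreign parameters keep an empty slot", {
  cr <- new_crate(deterministic_ids = TRUE)
  wf <- add_workflow(cr, "wf.cwl")
  add_data_entity(cr, "tool.cwl", c("SoftwareApplication", "File"))
  p_tool <- add_formal_parameter(cr, "tool.cwl", "input",
                                 param_spec("tool.cwl#in", "in"))
  add_data_entity(cr, "x.dat", "File")
  link_realization(cr, "x.dat", p_tool)
  # bound to a tool parameter, but used by the workflow-level action
  add_process_run(cr, run_spec(wf, inputs = "x.dat"))
  s <- action_report(cr)[[1L]]
  expect_identical(s$inputs[[1L]]$value, "x.dat")
  expect_true(is.na(s$inputs[[1L]]$parameter))
})

test_that("actions order by start time with missing times last, id tiebreak", {
  cr <- new_crate(deterministic_ids = TRUE)
  add_data_entity(cr, "#tool", "SoftwareApplication", in_root = FALSE)
  add_process_run(cr, run_spec("#tool"), id = "#z-notime")
  add_process_run(cr, run_spec("#tool"), id = "#a-notime")
  add_process_run(cr, run_spec("#tool", start = "2024-01-02T00:00:00+00:00"),
                  id = "#later")
  add_process_run(cr, run_spec("#tool", start = "2024-01-01T00:00:00+00:00"),
                  id = "#earlier")
  ids <- vapply(action_report(cr), `[[`, character(1), "action")
  expect_identical(ids, c("#earlier", "#later", "#a-notime", "#z-notime"))
})

test_that("the action table agrees with the report and keeps NA times", {
  cr <- fresh_fixture("pathology")
  q <- query_actions(cr)
  expect_identical(nrow(q), 4L)
  expect_setequal(q$action,
                  vapply(action_report(cr), `[[`, character(1), "action"))
  expect_false(anyNA(q$start))

  cr2 <- new_crate(deterministic_ids = TRUE)
  add_data_entity(cr2, "#tool", "SoftwareApplication", in_root = FALSE)
  add_process_run(cr2, run_spec("#tool", start = "2024-01-01T00:00:00+00:00"))
  q2 <- query_actions(cr2)
  expect_true(is.na(q2$end))
  expect_false(is.na(q2$start))
})

test_that("empty crates yield empty reports", {
  expect_length(action_report(new_crate()), 0L)
  expect_identical(nrow(query_actions(new_crate())), 0L)
})

test_that("parameter influence traversal matches the recorded connections", {
  cr <- fresh_fixture("pathology")
  hit <- affected_by(cr, "predictions.cwl#tissue-high-level")
  expect_identical(hit$step, "predictions.cwl#extract-tissue-high")
  expect_identical(hit$tool, "extract_tissue.cwl")
  expect_identical(hit$parameter, "extract_tissue.cwl#level")

  none <- affected_by(cr, "predictions.cwl#tissue")
  expect_identical(nrow(none), 0L)
  expect_error(affected_by(cr, "#nope"), "unknown parameter")
})

test_that("chained connections match a hand-computed closure", {
  cr <- new_crate(deterministic_ids = TRUE)
  wf <- add_workflow(cr, "wf.cwl")
  for (t in c("a.cwl", "b.cwl"))
    add_data_entity(cr, t, c("SoftwareApplication", "File"))
  wp <- add_formal_parameter(cr, wf, "input", param_spec("wf.cwl#in", "in"))
  a_in <- add_formal_parameter(cr, "a.cwl", "input",
                               param_spec("a.cwl#in", "in"))
  a_out <- add_formal_parameter(cr, "a.cwl", "output",
                                param_spec("a.cwl#out", "out"))
  b_in <- add_formal_parameter(cr, "b.cwl", "input",
                               param_spec("b.cwl#in", "in"))
  s1 <- add_step(cr, wf, "a.cwl", 0, "run-a")
  s2 <- add_step(cr, wf, "b.cwl", 1, "run-b")
  add_parameter_connection(cr, s1, wp, a_in)
  add_parameter_connection(cr, s1, a_in, a_out)
  add_parameter_connection(cr, s2, a_out, b_in)
  got <- affected_by(cr, wp)
  expect_identical(got$parameter, c("a.cwl#in", "a.cwl#out", "b.cwl#in"))
  expect_identical(got$tool, c("a.cwl", "a.cwl", "b.cwl"))
  expect_identical(got$step, c(s1, s1, s2))
})

test_that("downstream closure equals an independent BFS oracle", {
  for (name in c("head-sort", "cpm")) {
    cr <- fresh_fixture(name)
    starts <- switch(name, "head-sort" = "lines.txt",
                     cpm = c("cam16_mrxs.h5", "wsi/train/", "prov_train.log"))
    for (s in starts)
      expect_identical(sort(downstream_data(cr, s)), oracle_downstream(cr, s),
                       info = paste(name, s))
  }
})

test_that("implicit-workflow chains surface shared intermediates", {
  hs <- fresh_fixture("head-sort")
  expect_setequal(downstream_data(hs, "lines.txt"),
                  c("selection.txt", "sorted_selection.txt"))
  expect_length(downstream_data(hs, "sorted_selection.txt"), 0L)

  cpm <- fresh_fixture("cpm")
  down <- downstream_data(cpm, "cam16_mrxs.h5")
  expect_true(all(c("predictions.h5", "model/weights/auc_01.ckpt.index",
                    "prov_train.provn") %in% down))
  # the training log links the training run to its provenance-generation run
  tr <- entities_of_type(cpm, "CreateAction")
  out_of <- Filter(function(a) "prov_train.log" %in% prop_ids(a, "result"), tr)
  in_of <- Filter(function(a) "prov_train.log" %in% prop_ids(a, "object"), tr)
  expect_identical(out_of[[1L]]$id,
                   "#train_script:ROCRATE-PUB-1438b57a750ce887d4433d9e")
  expect_identical(in_of[[1L]]$id,
                   "#train_script:6efa9a06-b8e9-4cfc-88c7-e9d35e5263c3:CPM-provgen")
})

test_that("adding an action never removes reachability", {
  cr <- fresh_fixture("head-sort")
  before <- downstream_data(cr, "lines.txt")
  add_data_entity(cr, "extra.txt", "File")
  add_process_run(cr, run_spec("#sort", inputs = "sorted_selection.txt",
                               outputs = "extra.txt"))
  after <- downstream_data(cr, "lines.txt")
  expect_true(all(before %in% after))
  expect_true("extra.txt" %in% after)
})
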