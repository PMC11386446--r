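#' Example crate: manual head/sort runs
#'
#' A Process Run Crate describing an "implicit workflow" executed by hand: a
#' user (John Doe) runs `head` to extract the first ten lines of
#' `lines.txt` into `selection.txt`, then runs `sort` on that file to
#' produce `sorted_selection.txt`. The two `CreateAction`s are connected
#' only by the shared intermediate file. Timestamps and ancillary values not
#' part of the example narrative are flagged `wrroc:synthetic` in
#' `description` fields.
#'
#' @return A `wrroc_crate`.
#' @export
make_head_sort_crate <- function() {
  cr <- new_crate(name = "head/sort manual runs", deterministic_ids = TRUE)
  declare_profile(cr, "process")
  add_data_entity(cr, "#head", "SoftwareApplication", name = "head",
                  description = "wrroc:synthetic", in_root = FALSE)
  add_data_entity(cr, "#sort", "SoftwareApplication", name = "sort",
                  description = "wrroc:synthetic", in_root = FALSE)
  add_data_entity(cr, "#john-doe", "Person", name = "John Doe",
                  in_root = FALSE)
  add_data_entity(cr, "lines.txt", "File")
  add_data_entity(cr, "selection.txt", "File")
  add_data_entity(cr, "sorted_selection.txt", "File")
  nlines <- add_non_file_value(cr, "lines", "10")
  add_process_run(cr, run_spec(
    instrument = "#head", inputs = c("lines.txt", nlines),
    outputs = "selection.txt", agent = "#john-doe",
    start = "2023-04-27T15:02:56+02:00", end = "2023-04-27T15:02:57+02:00",
    status = "Completed",
    description = "wrroc:synthetic times"), id = "#head-run")
  add_process_run(cr, run_spec(
    instrument = "#sort", inputs = "selection.txt",
    outputs = "sorted_selection.txt", agent = "#john-doe",
    start = "2023-04-27T15:04:02+02:00", end = "2023-04-27T15:04:03+02:00",
    status = "Completed",
    description = "wrroc:synthetic times"), id = "#sort-run")
  cr
}

#' Example crate: annotation workflow run
#'
#' A minimal Workflow Run Crate around the `#annotations` formal parameter
#' and the `final-annotations.tsv` file that realized it, with the
#' parameter's declared type, encoding format and requiredness and the
#' file's `contentSize` of `"14784"` (kept as a string so it round-trips
#' byte-exactly). A minimal main workflow and run action satisfy the
#' profile; these scaffolding entities are flagged `wrroc:synthetic`.
#'
#' @return A `wrroc_crate`.
#' @export
make_annotation_wrc <- function() {
  cr <- new_crate(name = "annotation workflow run", deterministic_ids = TRUE)
  declare_profile(cr, "workflow")
  wf <- add_workflow(cr, "annotations.cwl", language_hint = "cwl")
  crate_set_prop(cr, wf, "description", "wrroc:synthetic scaffolding workflow")
  add_formal_parameter(cr, wf, "output", param_spec(
    "#annotations", "annotations", additional_type = "File",
    encoding_format = "text/tab-separated-values", value_required = TRUE))
  add_data_entity(cr, "final-annotations.tsv", "File", contentSize = "14784")
  link_realization(cr, "final-annotations.tsv", "#annotations")
  add_process_run(cr, run_spec(
    instrument = wf, outputs = "final-annotations.tsv",
    start = "2023-05-02T09:00:00+00:00", end = "2023-05-02T09:05:00+00:00",
    status = "Completed",
    description = "wrroc:synthetic scaffolding run"), id = "#annotation-run")
  cr
}

pathology_pv <- function(cr, name, value, params) {
  id <- add_non_file_value(cr, name, value)
  for (p in params) link_realization(cr, id, p)
  id
}

#' Example crate: digital pathology inference run
#'
#' A Provenance Run Crate for a three-step CWL image annotation workflow
#' (`predictions.cwl`): low-resolution tissue extraction, high-resolution
#' tissue extraction (same tool, different magnification level) and tumor
#' classification. It records the workflow-level run plus the three tool
#' runs with their ids and timestamps, the MIRAX input slide as a
#' `Collection` (main data file plus additional-files directory, original
#' name kept in `alternateName`), `PropertyValue`s for the string/number
#' arguments, SHA1-named intermediate and output files, the `HowToStep`s
#' and `ControlAction`s, the full set of parameter connections (e.g. the
#' workflow's `tissue-high-level` onto the tool's `level`), and the engine
#' run (`OrganizeAction` with the `streamflow.yml` configuration).
#' Property values not determined by the recorded run report (file names,
#' the engine and operator entities) are flagged `wrroc:synthetic`.
#'
#' @return A `wrroc_crate`.
#' @export
make_pathology_prc <- function() {
  cr <- new_crate(name = "digital pathology predictions run",
                  deterministic_ids = TRUE)
  declare_profile(cr, "provenance")
  wf <- add_workflow(cr, "predictions.cwl", language_hint = "cwl")
  add_data_entity(cr, "extract_tissue.cwl", c("SoftwareApplication", "File"),
                  name = "extract_tissue")
  add_data_entity(cr, "classify_tumor.cwl", c("SoftwareApplication", "File"),
                  name = "classify_tumor")

  # workflow-level parameters, in run-report order
  wparams <- list(
    list("slide", "Collection"), list("tissue-low-label", "Text"),
    list("tissue-low-level", "Integer"), list("tissue-high-filter", "Text"),
    list("tissue-high-label", "Text"), list("tissue-high-level", "Integer"),
    list("tumor-filter", "Text"), list("tumor-label", "Text"),
    list("tumor-level", "Integer"))
  for (p in wparams)
    add_formal_parameter(cr, wf, "input", param_spec(
      paste0(wf, "#", p[[1]]), p[[1]], additional_type = p[[2]],
      value_required = TRUE))
  for (p in c("tissue", "tumor"))
    add_formal_parameter(cr, wf, "output", param_spec(
      paste0(wf, "#", p), p, additional_type = "File"))

  # tool-level parameters
  for (tool in c("extract_tissue.cwl", "classify_tumor.cwl")) {
    for (p in c("filter", "filter_slide", "label", "level", "src"))
      add_formal_parameter(cr, tool, "input", param_spec(
        paste0(tool, "#", p), p,
        additional_type = switch(p, level = "Integer",
                                 src = "Collection",
                                 filter_slide = "File", "Text")))
  }
  add_formal_parameter(cr, "extract_tissue.cwl", "output", param_spec(
    "extract_tissue.cwl#tissue", "tissue", additional_type = "File"))
  add_formal_parameter(cr, "classify_tumor.cwl", "output", param_spec(
    "classify_tumor.cwl#tumor", "tumor", additional_type = "File"))

  # MIRAX input slide: SHA1-named main file + additional-files directory
  sha <- "af0253d688f3409a2c6d24bf6b35df7c4e271292"
  add_data_entity(cr, sha, "File", description = "wrroc:synthetic name")
  add_data_entity(cr, paste0(sha, "_files/"), "Dataset",
                  description = "wrroc:synthetic name")
  slide <- add_collection(cr, c(sha, paste0(sha, "_files/")), main = sha,
                          id = paste0("#", sha))
  set_alternate_name(cr, slide, "slide.mrxs")
  set_alternate_name(cr, sha, "slide.mrxs")
  for (p in c("predictions.cwl#slide", "extract_tissue.cwl#src",
              "classify_tumor.cwl#src"))
    link_realization(cr, slide, p)

  # argument values shared between workflow-level and tool-level parameters
  pv <- c(
    pathology_pv(cr, "tissue-low-label", "tissue_low",
                 c("predictions.cwl#tissue-low-label", "extract_tissue.cwl#label")),
    pathology_pv(cr, "tissue-low-level", "9",
                 c("predictions.cwl#tissue-low-level", "extract_tissue.cwl#level")),
    pathology_pv(cr, "tissue-high-filter", "tissue_low>0.9",
                 c("predictions.cwl#tissue-high-filter", "extract_tissue.cwl#filter")),
    pathology_pv(cr, "tissue-high-label", "tissue_high",
                 c("predictions.cwl#tissue-high-label", "extract_tissue.cwl#label")),
    pathology_pv(cr, "tissue-high-level", "4",
                 c("predictions.cwl#tissue-high-level", "extract_tissue.cwl#level")),
    pathology_pv(cr, "tumor-filter", "tissue_low>0.99",
                 c("predictions.cwl#tumor-filter", "classify_tumor.cwl#filter")),
    pathology_pv(cr, "tumor-label", "tumor",
                 c("predictions.cwl#tumor-label", "classify_tumor.cwl#label")),
    pathology_pv(cr, "tumor-level", "1",
                 c("predictions.cwl#tumor-level", "classify_tumor.cwl#level")))
  names(pv) <- c("tissue-low-label", "tissue-low-level", "tissue-high-filter",
                 "tissue-high-label", "tissue-high-level", "tumor-filter",
                 "tumor-label", "tumor-level")

  # SHA1-named intermediate and output files
  low_tissue <- "6b15de40dd0ee3234062d0f261c77575a60de0f2"
  out_tissue <- "06133ec5f8973ec3cc5281e5df56421c3228c221"
  out_tumor <- "4fd6110ee3c544182027f82ffe84b5ae7db5fb81"
  add_data_entity(cr, low_tissue, "File")
  add_data_entity(cr, out_tissue, "File")
  add_data_entity(cr, out_tumor, "File")
  set_alternate_name(cr, low_tissue, "tissue_low.tiff")
  set_alternate_name(cr, out_tissue, "tissue.tiff")
  set_alternate_name(cr, out_tumor, "tumor.tiff")
  for (p in c("extract_tissue.cwl#tissue", "extract_tissue.cwl#filter_slide",
              "classify_tumor.cwl#filter_slide"))
    link_realization(cr, low_tissue, p)
  link_realization(cr, out_tissue, "predictions.cwl#tissue")
  link_realization(cr, out_tissue, "extract_tissue.cwl#tissue")
  link_realization(cr, out_tumor, "predictions.cwl#tumor")
  link_realization(cr, out_tumor, "classify_tumor.cwl#tumor")

  # agent is not part of the run report; kept for PROV association coverage
  add_data_entity(cr, "#operator", "Person", name = "Crate Operator",
                  description = "wrroc:synthetic", in_root = FALSE)

  # the four recorded actions
  wf_run <- add_process_run(cr, run_spec(
    instrument = wf,
    inputs = c(slide, pv[["tissue-low-label"]], pv[["tissue-low-level"]],
               pv[["tissue-high-filter"]], pv[["tissue-high-label"]],
               pv[["tissue-high-level"]], pv[["tumor-filter"]],
               pv[["tumor-label"]], pv[["tumor-level"]]),
    outputs = c(out_tissue, out_tumor),
    agent = "#operator",
    start = "2023-05-09T05:10:53.937305+00:00",
    end = "2023-05-09T05:11:07.521396+00:00", status = "Completed"),
    id = "#30a65cba-1b75-47dc-ad47-1d33819cf156")
  low_run <- add_process_run(cr, run_spec(
    instrument = "extract_tissue.cwl",
    inputs = c(pv[["tissue-low-label"]], pv[["tissue-low-level"]], slide),
    outputs = low_tissue,
    start = "2023-05-09T05:10:55.236742+00:00",
    end = "2023-05-09T05:10:55.910025+00:00", status = "Completed"),
    id = "#457c80d0-75e8-46d6-bada-b3fe82ea0ef1")
  high_run <- add_process_run(cr, run_spec(
    instrument = "extract_tissue.cwl",
    inputs = c(pv[["tissue-high-filter"]], low_tissue,
               pv[["tissue-high-label"]], pv[["tissue-high-level"]], slide),
    outputs = out_tissue,
    start = "2023-05-09T05:10:58.417760+00:00",
    end = "2023-05-09T05:11:03.153912+00:00", status = "Completed"),
    id = "#d09a8355-1a14-4ea4-b00b-122e010e5cc9")
  tumor_run <- add_process_run(cr, run_spec(
    instrument = "classify_tumor.cwl",
    inputs = c(pv[["tumor-filter"]], low_tissue, pv[["tumor-label"]],
               pv[["tumor-level"]], slide),
    outputs = out_tumor,
    start = "2023-05-09T05:10:58.420654+00:00",
    end = "2023-05-09T05:11:06.708344+00:00", status = "Completed"),
    id = "#ae2163a8-1a2a-4d78-9c81-caad76a72e47")

  # prospective side: steps, step executions, engine run
  s_low <- add_step(cr, wf, "extract_tissue.cwl", 0, "extract-tissue-low")
  s_high <- add_step(cr, wf, "extract_tissue.cwl", 1, "extract-tissue-high")
  s_tumor <- add_step(cr, wf, "classify_tumor.cwl", 2, "classify-tumor")
  c_low <- add_step_execution(cr, s_low, low_run, id = "#control-0001")
  c_high <- add_step_execution(cr, s_high, high_run, id = "#control-0002")
  c_tumor <- add_step_execution(cr, s_tumor, tumor_run, id = "#control-0003")

  add_data_entity(cr, "#streamflow", "SoftwareApplication",
                  name = "StreamFlow", description = "wrroc:synthetic",
                  in_root = FALSE)
  add_data_entity(cr, "streamflow.yml", "File",
                  description = "wrroc:synthetic")
  add_engine_run(cr, "#streamflow", c(c_low, c_high, c_tumor), wf_run,
                 config = "streamflow.yml", id = "#organize-0001")

  # parameter connections: workflow slots onto tool slots, intermediate
  # outputs onto downstream inputs, tool outputs onto workflow outputs
  conns <- list(
    list(s_low, "predictions.cwl#slide", "extract_tissue.cwl#src"),
    list(s_low, "predictions.cwl#tissue-low-label", "extract_tissue.cwl#label"),
    list(s_low, "predictions.cwl#tissue-low-level", "extract_tissue.cwl#level"),
    list(s_high, "predictions.cwl#slide", "extract_tissue.cwl#src"),
    list(s_high, "predictions.cwl#tissue-high-filter", "extract_tissue.cwl#filter"),
    list(s_high, "predictions.cwl#tissue-high-label", "extract_tissue.cwl#label"),
    list(s_high, "predictions.cwl#tissue-high-level", "extract_tissue.cwl#level"),
    list(s_high, "extract_tissue.cwl#tissue", "extract_tissue.cwl#filter_slide"),
    list(s_tumor, "predictions.cwl#slide", "classify_tumor.cwl#src"),
    list(s_tumor, "predictions.cwl#tumor-filter", "classify_tumor.cwl#filter"),
    list(s_tumor, "predictions.cwl#tumor-label", "classify_tumor.cwl#label"),
    list(s_tumor, "predictions.cwl#tumor-level", "classify_tumor.cwl#level"),
    list(s_tumor, "extract_tissue.cwl#tissue", "classify_tumor.cwl#filter_slide"),
    list(wf, "extract_tissue.cwl#tissue", "predictions.cwl#tissue"),
    list(wf, "classify_tumor.cwl#tumor", "predictions.cwl#tumor"))
  for (i in seq_along(conns))
    add_parameter_connection(cr, conns[[i]][[1]], conns[[i]][[2]],
                             conns[[i]][[3]],
                             id = sprintf("#connection-%04d", i))

  # run-report order of the instrument types
  crate_set_types(cr, wf, c("SoftwareSourceCode", "ComputationalWorkflow",
                            "HowTo", "File"))
  cr
}

cpm_action <- function(cr, id, instrument, inputs, outputs, start, end) {
  add_process_run(cr, run_spec(
    instrument = instrument, inputs = inputs, outputs = outputs,
    start = start, end = end, status = "Completed",
    description = "wrroc:synthetic times"), id = id)
}

#' Example crate: AI training pipeline with CPM provenance files
#'
#' A Process Run Crate describing a carcinoma-detection model pipeline as an
#' implicit workflow of seven process runs: image conversion/preprocessing,
#' model testing and model training, plus four runs that convert the
#' pipeline logs into Common Provenance Model (provn) files and
#' meta-provenance. The chain is visible through shared entities, e.g.
#' `cam16_mrxs.h5` is output of the conversion run and input of both the
#' training and testing runs, and `prov_train.log` is output of the
#' training run and input of its provenance-generation run. The CPM files
#' themselves are included as plain data entities. Timestamps (absent from
#' the recorded report) are synthetic, in report order, and flagged as such.
#'
#' @return A `wrroc_crate`.
#' @export
make_cpm_process_crate <- function() {
  cr <- new_crate(name = "carcinoma detection training pipeline",
                  deterministic_ids = TRUE)
  declare_profile(cr, "process")
  for (s in c("convert_script", "test_script", "train_script",
              "log2prov_script", "meta_provn_script"))
    add_data_entity(cr, s, c("SoftwareApplication", "File"), name = s,
                    description = "wrroc:synthetic")
  add_data_entity(cr, "wsi/test/", "Dataset")
  add_data_entity(cr, "wsi/train/", "Dataset")
  files <- c(
    "prov_converter_config.json", "prov_test_config.json",
    "prov_train_config.json", "cam16_mrxs.h5", "prov_preprocess.log",
    "predictions.h5", "prov_test.log", "prov_test.provn",
    "prov_test.provn.log", "prov_test.png", "prov_train.log",
    "model/weights/auc_01.ckpt.index",
    "model/weights/auc_01.ckpt.data-00000-of-00001",
    "model/weights/auc_02.ckpt.index",
    "model/weights/auc_02.ckpt.data-00000-of-00001",
    "model/weights/best_loss.ckpt.index",
    "model/weights/best_loss.ckpt.data-00000-of-00001",
    "model/weights/auc_03.ckpt.index",
    "model/weights/auc_03.ckpt.data-00000-of-00001",
    "prov_train.provn", "prov_train.png", "prov_train.provn.log",
    "prov_preprocess.provn", "prov_preprocess.png",
    "prov_preprocess.provn.log", "meta_provenance.provn",
    "meta_provenance.png", "meta_provenance.provn.log")
  for (f in files) add_data_entity(cr, f, "File")

  cpm_action(cr, "#convert_script:ff67ce65-736f-46d5-9fec-10953cad8695",
             "convert_script",
             c("wsi/test/", "wsi/train/", "prov_converter_config.json"),
             c("cam16_mrxs.h5", "prov_preprocess.log"),
             "2023-06-01T10:00:00+00:00", "2023-06-01T10:10:00+00:00")
  cpm_action(cr, "#test_script:ROCRATE-PUB-1438b57a750ce887d4433d9e",
             "test_script",
             c("prov_test_config.json", "cam16_mrxs.h5"),
             c("predictions.h5", "prov_test.log"),
             "2023-06-01T10:20:00+00:00", "2023-06-01T10:30:00+00:00")
  cpm_action(cr, "#test_script:d3cfd9cf-6851-43c6-bee9-c8dc18f22368:CPM-provgen",
             "log2prov_script",
             "prov_test.log",
             c("prov_test.provn", "prov_test.provn.log", "prov_test.png"),
             "2023-06-01T10:40:00+00:00", "2023-06-01T10:41:00+00:00")
  cpm_action(cr, "#train_script:ROCRATE-PUB-1438b57a750ce887d4433d9e",
             "train_script",
             c("prov_train_config.json", "cam16_mrxs.h5"),
             c("prov_train.log",
               "model/weights/auc_01.ckpt.index",
               "model/weights/auc_01.ckpt.data-00000-of-00001",
               "model/weights/auc_02.ckpt.index",
               "model/weights/auc_02.ckpt.data-00000-of-00001",
               "model/weights/best_loss.ckpt.index",
               "model/weights/best_loss.ckpt.data-00000-of-00001",
               "model/weights/auc_03.ckpt.index",
               "model/weights/auc_03.ckpt.data-00000-of-00001"),
             "2023-06-01T10:50:00+00:00", "2023-06-01T11:50:00+00:00")
  cpm_action(cr, "#train_script:6efa9a06-b8e9-4cfc-88c7-e9d35e5263c3:CPM-provgen",
             "log2prov_script",
             "prov_train.log",
             c("prov_train.provn", "prov_train.png", "prov_train.provn.log"),
             "2023-06-01T12:00:00+00:00", "2023-06-01T12:01:00+00:00")
  cpm_action(cr, "#convert_script:9d030b68-70d8-4526-82fe-160d9cfe4806:CPM-provgen",
             "log2prov_script",
             "prov_preprocess.log",
             c("prov_preprocess.provn", "prov_preprocess.png",
               "prov_preprocess.provn.log"),
             "2023-06-01T12:10:00+00:00", "2023-06-01T12:11:00+00:00")
  cpm_action(cr, "#meta_provn_script:86bae258-4c51-4215-854b-32cb49f239ab:CPM-provgen",
             "meta_provn_script",
             c("prov_train.provn.log", "prov_test.provn.log",
               "prov_preprocess.provn.log"),
             c("meta_provenance.provn", "meta_provenance.png",
               "meta_provenance.provn.log"),
             "2023-06-01T12:20:00+00:00", "2023-06-01T12:21:00+00:00")
  cr
}

#' Random provenance crate with known input bindings
#'
#' Property-test generator: builds a seeded random Provenance Run Crate with
#' `n_steps` tool executions and `n_params` workflow input parameters, each
#' bound to either a literal `PropertyValue` or a file (sometimes carrying
#' an `alternateName`). Identical seeds yield identical crates. The returned
#' ground truth maps each parameter name to what a re-execution planner must
#' recover.
#'
#' @param seed Integer seed.
#' @param n_steps Number of steps/tool runs.
#' @param n_params Number of workflow input parameters.
#' @return List with elements `crate` and `bindings` (named list of
#'   `list(kind, value/source, name)`).
#' @export
make_random_run <- function(seed, n_steps = 2, n_params = 3) {
  set.seed(seed)
  cr <- new_crate(name = sprintf("random run %d", seed),
                  deterministic_ids = TRUE)
  declare_profile(cr, "provenance")
  wf <- add_workflow(cr, "wf.cwl", language_hint = "cwl")

  truth <- list()
  inputs <- character()
  for (i in seq_len(n_params)) {
    pname <- sprintf("p%02d", i)
    pid <- add_formal_parameter(cr, wf, "input", param_spec(
      paste0(wf, "#", pname), pname,
      additional_type = "Text", value_required = TRUE))
    if (stats::runif(1) < 0.5) {
      val <- as.character(sample.int(1000L, 1L))
      vid <- add_non_file_value(cr, pname, val)
      truth[[pname]] <- list(kind = "literal", value = val)
    } else {
      vid <- add_data_entity(cr, sprintf("data/in-%02d.dat", i), "File")
      b <- list(kind = "file", source = vid)
      if (stats::runif(1) < 0.5) {
        nm <- sprintf("original-%02d.dat", i)
        set_alternate_name(cr, vid, nm)
        b$name <- nm
      }
      truth[[pname]] <- b
    }
    link_realization(cr, vid, pid)
    inputs <- c(inputs, vid)
  }

  out_param <- add_formal_parameter(cr, wf, "output", param_spec(
    paste0(wf, "#out"), "out", additional_type = "File"))
  final_out <- add_data_entity(cr, "data/out.dat", "File")
  link_realization(cr, final_out, out_param)

  wf_run <- add_process_run(cr, run_spec(
    instrument = wf, inputs = inputs, outputs = final_out,
    start = "2024-03-01T08:00:00+00:00",
    end = "2024-03-01T09:00:00+00:00", status = "Completed"))

  controls <- character()
  for (i in seq_len(n_steps)) {
    tool <- add_data_entity(cr, sprintf("tool-%02d.cwl", i),
                            c("SoftwareApplication", "File"))
    step <- add_step(cr, wf, tool, i - 1L, sprintf("run-tool-%02d", i))
    inter <- add_data_entity(cr, sprintf("data/inter-%02d.dat", i), "File")
    act <- add_process_run(cr, run_spec(
      instrument = tool,
      inputs = if (length(inputs)) inputs[[1L + (i - 1L) %% length(inputs)]]
               else character(),
      outputs = inter,
      start = sprintf("2024-03-01T08:%02d:00+00:00", i),
      end = sprintf("2024-03-01T08:%02d:30+00:00", i),
      status = "Completed"))
    controls <- c(controls, add_step_execution(cr, step, act))
  }
  add_data_entity(cr, "#engine", "SoftwareApplication", name = "engine",
                  in_root = FALSE)
  add_engine_run(cr, "#engine", controls, wf_run)

  list(crate = cr, bindings = truth)
}
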