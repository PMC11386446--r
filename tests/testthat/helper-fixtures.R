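# Crates are mutable environments, so fixtures are always built fresh.
fresh_fixture <- function(name) {
  switch(name,
         "head-sort" = make_head_sort_crate(),
         annotation = make_annotation_wrc(),
         pathology = make_pathology_prc(),
         cpm = make_cpm_process_crate(),
         stop("unknown fixture: ", name))
}

# Transcription of the published run report for the digital pathology
# Provenance Run Crate (the workflow run plus three tool runs).
pathology_report_golden <- function() {
  paste(c(
    "action: #30a65cba-1b75-47dc-ad47-1d33819cf156",
    " instrument: predictions.cwl (['SoftwareSourceCode', 'ComputationalWorkflow', 'HowTo', 'File'])",
    " started: 2023-05-09T05:10:53.937305+00:00",
    " ended: 2023-05-09T05:11:07.521396+00:00",
    " inputs:",
    "  #af0253d688f3409a2c6d24bf6b35df7c4e271292 <- predictions.cwl#slide",
    "  tissue_low <- predictions.cwl#tissue-low-label",
    "  9 <- predictions.cwl#tissue-low-level",
    "  tissue_low>0.9 <- predictions.cwl#tissue-high-filter",
    "  tissue_high <- predictions.cwl#tissue-high-label",
    "  4 <- predictions.cwl#tissue-high-level",
    "  tissue_low>0.99 <- predictions.cwl#tumor-filter",
    "  tumor <- predictions.cwl#tumor-label",
    "  1 <- predictions.cwl#tumor-level",
    " outputs:",
    "  06133ec5f8973ec3cc5281e5df56421c3228c221 <- predictions.cwl#tissue",
    "  4fd6110ee3c544182027f82ffe84b5ae7db5fb81 <- predictions.cwl#tumor",
    "action: #457c80d0-75e8-46d6-bada-b3fe82ea0ef1",
    " step: predictions.cwl#extract-tissue-low",
    " instrument: extract_tissue.cwl (['SoftwareApplication', 'File'])",
    " started: 2023-05-09T05:10:55.236742+00:00",
    " ended: 2023-05-09T05:10:55.910025+00:00",
    " inputs:",
    "  tissue_low <- extract_tissue.cwl#label",
    "  9 <- extract_tissue.cwl#level",
    "  #af0253d688f3409a2c6d24bf6b35df7c4e271292 <- extract_tissue.cwl#src",
    " outputs:",
    "  6b15de40dd0ee3234062d0f261c77575a60de0f2 <- extract_tissue.cwl#tissue",
    "action: #d09a8355-1a14-4ea4-b00b-122e010e5cc9",
    " step: predictions.cwl#extract-tissue-high",
    " instrument: extract_tissue.cwl (['SoftwareApplication', 'File'])",
    " started: 2023-05-09T05:10:58.417760+00:00",
    " ended: 2023-05-09T05:11:03.153912+00:00",
    " inputs:",
    "  tissue_low>0.9 <- extract_tissue.cwl#filter",
    "  6b15de40dd0ee3234062d0f261c77575a60de0f2 <- extract_tissue.cwl#filter_slide",
    "  tissue_high <- extract_tissue.cwl#label",
    "  4 <- extract_tissue.cwl#level",
    "  #af0253d688f3409a2c6d24bf6b35df7c4e271292 <- extract_tissue.cwl#src",
    " outputs:",
    "  06133ec5f8973ec3cc5281e5df56421c3228c221 <- extract_tissue.cwl#tissue",
    "action: #ae2163a8-1a2a-4d78-9c81-caad76a72e47",
    " step: predictions.cwl#classify-tumor",
    " instrument: classify_tumor.cwl (['SoftwareApplication', 'File'])",
    " started: 2023-05-09T05:10:58.420654+00:00",
    " ended: 2023-05-09T05:11:06.708344+00:00",
    " inputs:",
    "  tissue_low>0.99 <- classify_tumor.cwl#filter",
    "  6b15de40dd0ee3234062d0f261c77575a60de0f2 <- classify_tumor.cwl#filter_slide",
    "  tumor <- classify_tumor.cwl#label",
    "  1 <- classify_tumor.cwl#level",
    "  #af0253d688f3409a2c6d24bf6b35df7c4e271292 <- classify_tumor.cwl#src",
    " outputs:",
    "  4fd6110ee3c544182027f82ffe84b5ae7db5fb81 <- classify_tumor.cwl#tumor"),
    collapse = "\n")
}

# Transcription of the published run report for the AI training pipeline,
# restricted to the action/inputs/outputs structure it shows.
cpm_report_structure_golden <- function() {
  c("action: #convert_script:ff67ce65-736f-46d5-9fec-10953cad8695",
    " inputs:", "  wsi/test/", "  wsi/train/", "  prov_converter_config.json",
    " outputs:", "  cam16_mrxs.h5", "  prov_preprocess.log",
    "action: #test_script:ROCRATE-PUB-1438b57a750ce887d4433d9e",
    " inputs:", "  prov_test_config.json", "  cam16_mrxs.h5",
    " outputs:", "  predictions.h5", "  prov_test.log",
    "action: #test_script:d3cfd9cf-6851-43c6-bee9-c8dc18f22368:CPM-provgen",
    " inputs:", "  prov_test.log",
    " outputs:", "  prov_test.provn", "  prov_test.provn.log", "  prov_test.png",
    "action: #train_script:ROCRATE-PUB-1438b57a750ce887d4433d9e",
    " inputs:", "  prov_train_config.json", "  cam16_mrxs.h5",
    " outputs:", "  prov_train.log",
    "  model/weights/auc_01.ckpt.index",
    "  model/weights/auc_01.ckpt.data-00000-of-00001",
    "  model/weights/auc_02.ckpt.index",
    "  model/weights/auc_02.ckpt.data-00000-of-00001",
    "  model/weights/best_loss.ckpt.index",
    "  model/weights/best_loss.ckpt.data-00000-of-00001",
    "  model/weights/auc_03.ckpt.index",
    "  model/weights/auc_03.ckpt.data-00000-of-00001",
    "action: #train_script:6efa9a06-b8e9-4cfc-88c7-e9d35e5263c3:CPM-provgen",
    " inputs:", "  prov_train.log",
    " outputs:", "  prov_train.provn", "  prov_train.png", "  prov_train.provn.log",
    "action: #convert_script:9d030b68-70d8-4526-82fe-160d9cfe4806:CPM-provgen",
    " inputs:", "  prov_preprocess.log",
    " outputs:", "  prov_preprocess.provn", "  prov_preprocess.png",
    "  prov_preprocess.provn.log",
    "action: #meta_provn_script:86bae258-4c51-4215-854b-32cb49f239ab:CPM-provgen",
    " inputs:", "  prov_train.provn.log", "  prov_test.provn.log",
    "  prov_preprocess.provn.log",
    " outputs:", "  meta_provenance.provn", "  meta_provenance.png",
    "  meta_provenance.provn.log")
}

report_structure_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines[grepl("^(action: | inputs:| outputs:|  )", lines)]
}

# Minimal metadata document embedding the formal-parameter / realized-file
# pair from the workflow-profile documentation example.
annotation_snippet_json <- function() {
'{
  "@context": "https://w3id.org/ro/crate/1.1/context",
  "@graph": [
    {
      "@id": "ro-crate-metadata.json",
      "@type": "CreativeWork",
      "about": {"@id": "./"},
      "conformsTo": {"@id": "https://w3id.org/ro/crate/1.1"}
    },
    {
      "@id": "./",
      "@type": "Dataset",
      "hasPart": {"@id": "final-annotations.tsv"}
    },
    {
      "@id": "#annotations",
      "@type": "FormalParameter",
      "additionalType": "File",
      "encodingFormat": "text/tab-separated-values",
      "valueRequired": "True",
      "name": "annotations"
    },
    {
      "@id": "final-annotations.tsv",
      "@type": "File",
      "contentSize": "14784",
      "exampleOfWork": {"@id": "#annotations"}
    }
  ]
}'
}

# Independent dependency-closure oracle: parses the serialized document with
# jsonlite (bypassing the package accessors), extracts result->action->object
# edges and runs a plain BFS.
oracle_downstream <- function(crate, start) {
  doc <- jsonlite::fromJSON(write_crate(crate), simplifyVector = FALSE)
  ids_of <- function(node, key) {
    v <- node[[key]]
    if (is.null(v)) return(character())
    if (!is.null(names(v)) && "@id" %in% names(v)) return(v[["@id"]])
    unlist(lapply(v, function(x) if (is.list(x)) x[["@id"]] else NULL))
  }
  actions <- Filter(function(n) "CreateAction" %in% unlist(n[["@type"]]),
                    doc[["@graph"]])
  edges <- list()
  for (a in actions)
    edges[[length(edges) + 1L]] <- list(from = ids_of(a, "object"),
                                        to = ids_of(a, "result"))
  reached <- character(); frontier <- start
  while (length(frontier)) {
    nxt <- character()
    for (e in edges)
      if (any(frontier %in% e$from))
        for (r in e$to)
          if (r != start && !r %in% reached) {
            reached <- c(reached, r); nxt <- c(nxt, r)
          }
    frontier <- nxt
  }
  sort(reached)
}
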