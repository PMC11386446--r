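Package: wrroc
Title: Build, Validate and Query Workflow Run RO-Crates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with RO-Crates that describe computational runs
    following the Process Run Crate, Workflow Run Crate and Provenance Run
    Crate profiles. Reads and writes the flattened JSON-LD metadata document,
    offers a builder API for recording process, workflow and provenance runs,
    validates crates against the profile hierarchy, reports on the recorded
    executions, exports run descriptions to W3C PROV, and generates
    engine-neutral re-execution plans from recorded input bindings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
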