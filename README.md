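# wrroc

Build, validate and query **Workflow Run RO-Crates** in R.

Computational analyses increasingly need to ship with their provenance:
what was run, on which inputs, by whom, when, and how the pieces connect.
The workflow-run RO-Crate profiles answer this with a single flattened
JSON-LD metadata document (`ro-crate-metadata.json`) describing runs at
three nested levels of detail — **Process Run Crate** (executions of
individual applications, possibly forming an implicit workflow through
shared files), **Workflow Run Crate** (adds the workflow definition and its
formal parameters), and **Provenance Run Crate** (adds steps, step
executions, the engine run and parameter connections). This package is a
standalone toolkit for that model, aimed at workflow-engine developers
adding crate export, and at analysts consuming crates produced by engines
such as cwltool, StreamFlow or Galaxy.

At its core is the schema.org action model: each execution is a

```
CreateAction --instrument--> SoftwareApplication | ComputationalWorkflow
             --object-----> inputs  (File | Collection | PropertyValue)
             --result-----> outputs
             --agent------> Person | Organization
```

with the retrospective values tied to the prospective parameter slots
(`bioschemas:FormalParameter`, declared via `bsp:input`/`bsp:output`)
through `s:exampleOfWork`, and data flow between slots recorded as
`wfrun:ParameterConnection`s. On top of the graph model the package
provides:

* `read_crate()` / `write_crate()` — bit-careful, deterministic JSON-LD
  I/O (strings like `"14784"` survive byte-exactly; two writes of one
  crate are identical)
* a builder API — `add_process_run()`, `add_workflow()`,
  `add_formal_parameter()`, `link_realization()`, `add_step()`,
  `add_parameter_connection()`, `add_collection()`, ...
* `validate_crate()` — MUST/SHOULD findings against the profile
  hierarchy, with a mutation catalog proving each rule fires
* `action_report()`, `query_actions()`, `affected_by()`,
  `downstream_data()` — run summaries and provenance traversals
* `to_prov()` — export to W3C PROV (N-Triples / PROV-N) via the published
  SKOS-annotated term mapping
* `rerun_plan()` / `emit_job_document()` — recover the input bindings of
  a recorded run as an engine-neutral job document
* fixture generators for the model's worked examples, and a `wrroc`
  command line (`exec/wrroc`) with `validate`, `report`, `query`, `prov`,
  `rerun-plan` and `example` subcommands.

## Worked example

Record two manual runs — `head` then `sort`, chained through
`selection.txt` — and query the implicit workflow:

```r
library(wrroc)

crate <- make_head_sort_crate()   # or build it yourself with the builder API
downstream_data(crate, "lines.txt")
#> [1] "selection.txt"        "sorted_selection.txt"

is_conformant(validate_crate(crate, "process"))
#> [1] TRUE
```

The digital pathology example ships as a full Provenance Run Crate: a
three-step CWL workflow (two tissue-extraction runs at different
magnification levels plus a tumor classification run):

```r
crate <- make_pathology_prc()
print(action_report(crate))
#> action: #30a65cba-1b75-47dc-ad47-1d33819cf156
#>  instrument: predictions.cwl (['SoftwareSourceCode', 'ComputationalWorkflow', 'HowTo', 'File'])
#>  started: 2023-05-09T05:10:53.937305+00:00
#>  ended: 2023-05-09T05:11:07.521396+00:00
#>  inputs:
#>   #af0253d688f3409a2c6d24bf6b35df7c4e271292 <- predictions.cwl#slide
#>   tissue_low <- predictions.cwl#tissue-low-label
#>   9 <- predictions.cwl#tissue-low-level
#>   ...
```

(four actions in all: the workflow run and its three tool runs). The
parameter-connection traversal answers "which tool does this workflow
parameter affect":

```r
affected_by(crate, "predictions.cwl#tissue-high-level")
#>                                  step               tool                parameter
#> 1 predictions.cwl#extract-tissue-high extract_tissue.cwl extract_tissue.cwl#level
```

and the recorded input bindings invert into a re-execution job document,
with original file names restored from `alternateName`:

```r
cat(emit_job_document(rerun_plan(crate)))
#> {
#>   "slide": {
#>     "class": "Collection",
#>     "path": "slide.mrxs",
#>     "mainEntity": "af0253d688f3409a2c6d24bf6b35df7c4e271292"
#>   },
#>   "tissue-high-filter": "tissue_low>0.9",
#>   ...
#> }
```

From a shell, the same over a crate directory:

```sh
exec/wrroc validate my-crate/            # exit 1 on MUST-level findings
exec/wrroc report my-crate/
exec/wrroc prov --format ntriples my-crate/
```

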