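---
title: "Modelling workflow execution provenance with run crates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling workflow execution provenance with run crates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrroc)
```

## The model

An RO-Crate is a directory of research artefacts described by a single
flattened JSON-LD document (`ro-crate-metadata.json`): a `@context` naming
the vocabulary and a flat `@graph` of entities, each with an `@id`, one or
more types, and properties whose values are literals or `{"@id": ...}`
references. The workflow-run profiles layer a provenance model on top of
this, in three nested levels:

* **Process Run Crate.** Each execution of an application is a
  `CreateAction` pointing at the application via `instrument`, at its
  inputs via `object` and outputs via `result`, with `startTime`,
  `endTime`, `agent`, `actionStatus` and `error` as recorded.
  Non-file arguments (numbers, strings) are `PropertyValue` entities.
  Several runs connected only through shared files form an *implicit
  workflow*: nothing orchestrates them, but the data flow is recoverable.
* **Workflow Run Crate.** Adds the *prospective* side: a main workflow
  typed `File` + `SoftwareSourceCode` + `ComputationalWorkflow`, declaring
  its input and output slots as `FormalParameter`s (via `input`/`output`).
  The retrospective values link back to the slots they realized through
  `exampleOfWork` — the property this whole package pivots on: it is what
  lets a consumer pair "the value `9`" with "the parameter
  `tissue-low-level`".
* **Provenance Run Crate.** Adds the workflow's inner structure: steps
  (`HowToStep`, pointing at tools via `workExample`), step executions
  (`ControlAction`), the engine run (`OrganizeAction`, whose `object` may
  include a configuration file), and `ParameterConnection`s that map
  workflow-level slots onto tool-level slots and tool outputs onto
  downstream tool inputs.

The three profiles form a strict subset hierarchy (provenance ⊃ workflow ⊃
process), which the validator honours: validating against a deeper profile
always applies the shallower rule sets too.

## Reading and writing: why not full JSON-LD

`read_crate()`/`write_crate()` deliberately avoid general JSON-LD
processing (expansion, context resolution). Run crates in the wild use the
standard RO-Crate context plus the workflow-run term set; treating the
document as that fixed, flattened dialect keeps terms stable and makes a
bit-exact round trip possible. Concretely:

* Literals are never coerced: a `contentSize` of `"14784"` stays the
  string `"14784"`.
* Single values and one-element lists are semantically identical; the
  model normalizes to lists internally and writes singletons back as
  single values.
* Ids are compared by exact string equality, never rewritten, and an
  unrecognized `@context` is kept verbatim with a recorded note.
* Output is deterministic: descriptor, root, then entities by id; keys
  ordered `@id`, `@type`, then alphabetically. Two writes of the same
  crate are byte-identical, which is what makes golden-file testing and
  diffing crates meaningful.

External URIs are legal reference targets that need not resolve inside the
graph; `dangling_refs()` reports them with an `external` flag instead of
rejecting them, since data entities may intentionally be remote.

## Builder conventions

The builder records runs without inventing anything: timestamps are
caller-supplied ISO 8601 strings stored verbatim, `object`/`result` order
is preserved as given (it is meaningful to readers of the report), and an
`error` may only accompany a failed status. Generated ids are v4-format
UUIDs prefixed with `#`; fixtures and tests use either explicit ids or the
reproducible `#action-0001` scheme (`new_crate(deterministic_ids =
TRUE)`), so that building the same crate twice yields byte-identical
documents. `PropertyValue` ids follow a deterministic `#<name>-pv` pattern
with numeric suffixes on collision, never silent overwrites.

Two conventions were genuinely open and are package choices:

* Profile conformance is *written* to the root dataset's `conformsTo`;
  detection reads both the root and the metadata descriptor, since both
  placements occur in practice. Detection is version-tolerant within the
  0.x family and notes a mismatch against the pinned version (0.5).
* A parameter connection is attached to exactly one holder (the step, or
  the workflow for workflow-output connections); when a connection could
  logically belong to several holders the builder does not guess.

## The validator

The profiles state their constraints in prose; the rule catalog here
(P1–P4, W1–W4, V1–V6, documented under `validate_crate()`) is this
package's codification of them into checkable MUST/SHOULD rules. Findings
are data, not exceptions — a data frame of (rule id, severity, entity,
message) — and a crate conforms iff its MUST subset is empty. Two rules
rank requirements the profiles leave soft: `agent` is not required (engine
generated crates often lack a person), and membership of `object`/`result`
in the data-entity types is SHOULD-level (P3). Every rule is paired with a
mutation in `mutation_catalog()` that triggers it and only it, which keeps
the catalog honest as rules evolve.

## Reports and traversals

`action_report()` orders actions by parsed start time, with ties and
missing or unparseable times falling back to id order and timeless actions
last. (On the shipped pathology fixture this coincides with printing the
workflow run first; the ordering rule, not the listing, is the contract.)
Value/parameter pairing is restricted to parameters owned by the action's
instrument: when one entity realizes parameters of several tools — the
MIRAX slide collection realizes the workflow's `slide` and both tools'
`src` — each action reports only the slot its own instrument owns, and a
value with no owned slot is shown with an empty parameter rather than a
guessed one.

`downstream_data()` follows the implicit-workflow relation
(entity → consuming action → produced entities) by breadth-first search;
`affected_by()` follows `ParameterConnection` edges transitively from a
workflow-level slot and reports (step, tool, parameter) hops in traversal
order. Both are pure functions of the document.

## PROV export

`to_prov()` implements the published crate-to-PROV correspondence, which
`mapping_table()` exposes as data together with each pair's SKOS strength.
Only `exact`, `close` and `broader` rows become triples: actions are typed
`prov:Activity`; `object` becomes `prov:used` and `result` the inverse of
`prov:wasGeneratedBy`; agents get `prov:wasAssociatedWith` plus
`prov:Person`/`prov:Organization` typing; workflows, tools and steps are
typed both `prov:Plan` and `prov:Entity`; timestamps become
`prov:startedAtTime`/`prov:endedAtTime`, typed `xsd:dateTime` when they
parse. When an action has both an agent and an instrument, a qualified
`prov:Association` node carries `prov:hadPlan` to the instrument; its id
derives deterministically from the action id. Two deliberate omissions:
the engine run's links to `ControlAction`s are *not* exported as `used`
(activities cannot be used in PROV, and the mapping defines no equivalent)
but recorded as per-export annotations; and the `related`-strength rows
(`SoftwareApplication` ~ `prov:SoftwareAgent`, `agent` ~
`wasStartedBy`/`wasEndedBy`) are carried as annotations only — the mapping
does not state that start/end attribution should be asserted, so it is
not. Crate-local ids are resolved against the `arcp://wrroc/` base to form
absolute IRIs; N-Triples output is sorted and byte-deterministic.

## Re-execution plans

`rerun_plan()` inverts the builder: for each workflow input slot it finds
the unique member of the run action's `object` whose `exampleOfWork`
includes that slot. Missing realizations are errors for required
parameters (`valueRequired` other than `"False"`), omissions otherwise;
two candidates are an ambiguity error, never a silent pick; action objects
with no parameter link at all (as produced by systems that do not track
slots) are surfaced in `unbound_values` and never matched by name. The
plan deliberately stops short of execution — re-running needs an engine
and containers, and reproducibility can only be supported, not ensured, by
metadata — so `emit_job_document()` renders an engine-neutral, key-sorted
JSON job order in which `alternateName`s replace content-derived file
names (restoring names matters for formats like MIRAX where the main file
and its sidecar directory must share a basename). Output parameters are
listed but never bound.

## Fixtures and the random generator

The four fixture builders reproduce the model's published worked examples
as code: the manual head/sort chain, the annotation-parameter snippet, the
digital pathology provenance crate (four actions, three steps, fifteen
parameter connections, a MIRAX collection input) and the seven-action AI
training pipeline with its provenance-file generation runs. Values the
examples print — ids, timestamps, parameter names, the `"14784"` content
size — are transcribed verbatim; everything the profiles require but the
examples do not show (engine and operator entities, file original names,
timestamps for the training pipeline, which prints none) is synthetic and
flagged `wrroc:synthetic` in `description` fields, and golden comparisons
exclude it: the training-pipeline report is compared only on the
action/inputs/outputs structure the example actually shows, with synthetic
times chosen to preserve its print order.

`make_random_run()` emulates the structural shape of engine-exported
provenance crates — a workflow with literal and file inputs (files
sometimes carrying an `alternateName`), steps, step executions and an
engine run — with a known ground-truth binding map for property tests.
It does not emulate real-data features such as deep nesting, scattered
steps with multiple executions, remote data entities, failed runs or
vocabulary noise from foreign contexts; passing its 200-seed recovery and
round-trip suites therefore demonstrates the inversion and serialization
machinery, not robustness to arbitrary crates in the wild. Test and
acceptance runs use 200 seeded crates of 1–3 steps and 0–4 parameters and
complete in seconds; the counts are a package choice balancing coverage
against suite runtime.

## Known limitations

* No general JSON-LD: documents using a materially different context are
  read term-for-term, with a note, not re-interpreted.
* Payload files are never checksummed, fetched or verified; the model is
  metadata-only, and `example` payloads are placeholders.
* Only the fixed all-actions traversal is provided natively; arbitrary
  graph queries belong in an RDF store loaded from the PROV export.
* PROV import, PROV-XML/JSON dialects and engine integration are out of
  scope.
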