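SOFTWARE_TYPES <- c("SoftwareApplication", "SoftwareSourceCode",
                    "ComputationalWorkflow")
COMPLETED <- "CompletedActionStatus"
FAILED <- "FailedActionStatus"

#' Describe one recorded execution
#'
#' Collects everything the builder needs to record a run as a `CreateAction`:
#' the application that was executed (`instrument`), who ran it (`agent`),
#' the actual inputs and outputs, timing, status and an optional error
#' message. Timestamps are caller-supplied ISO 8601 strings stored verbatim;
#' the builder never invents times.
#'
#' @param instrument Id of the executed application (software-typed entity).
#' @param inputs,outputs Character vectors of entity ids used / produced.
#' @param agent Optional id of the `Person`/`Organization` that ran it.
#' @param start,end Optional ISO 8601 timestamps with offset.
#' @param status One of `"Completed"`, `"Failed"`, or `NA` (unset).
#' @param error Optional error message; only allowed with `status = "Failed"`.
#' @param description Optional free-text description.
#' @return A `wrroc_run_spec`.
#' @export
run_spec <- function(instrument, inputs = character(), outputs = character(),
                     agent = NULL, start = NULL, end = NULL,
                     status = NA_character_, error = NULL, description = NULL) {
  if (!is.na(status) && !status %in% c("Completed", "Failed"))
    stop("status must be Completed, Failed or NA", call. = FALSE)
  if (!is.null(error) && (is.na(status) || status != "Failed"))
    stop("`error` may only be set when status is Failed", call. = FALSE)
  if (!is.null(start) && !is.null(end)) {
    ps <- parse_time(start); pe <- parse_time(end)
    if (!is.na(ps) && !is.na(pe) && ps > pe)
      stop("start time is after end time", call. = FALSE)
  }
  structure(list(instrument = instrument, inputs = as.character(inputs),
                 outputs = as.character(outputs), agent = agent,
                 start = start, end = end, status = status, error = error,
                 description = description),
            class = "wrroc_run_spec")
}

#' Describe a formal parameter
#'
#' A formal parameter is a declared input or output slot of a workflow or
#' tool (`FormalParameter`); at run time it is realized by a data entity or
#' `PropertyValue` via the `exampleOfWork` link.
#'
#' @param id Parameter id, conventionally `<owner-id>#<name>`.
#' @param name Parameter name.
#' @param additional_type Value type, e.g. `"File"`, `"Integer"`, `"Text"`,
#'   `"Collection"`.
#' @param encoding_format Optional media type of file values.
#' @param value_required Optional logical; unbound required inputs make
#'   re-execution planning fail.
#' @return A `wrroc_param_spec`.
#' @export
param_spec <- function(id, name, additional_type = "Text",
                       encoding_format = NULL, value_required = NULL) {
  check_entity_id(id)
  if (!nzchar(name)) stop("parameter name must be non-empty", call. = FALSE)
  structure(list(id = id, name = name, additional_type = additional_type,
                 encoding_format = encoding_format,
                 value_required = value_required),
            class = "wrroc_param_spec")
}

require_entity <- function(crate, id, what = "entity") {
  e <- resolve(crate, id)
  if (is.null(e)) stop(what, " not in crate: ", dQuote(id), call. = FALSE)
  e
}

mention <- function(crate, id) {
  if (!id %in% prop_ids(crate_root(crate), "mentions"))
    crate_append_prop(crate, crate$root_id, "mentions", ref(id))
}

#' Record a process run
#'
#' Creates the `CreateAction` describing one execution: `instrument` links to
#' the application, `object` to the inputs, `result` to the outputs, `agent`
#' to the person or organization that performed it, with `startTime`/
#' `endTime`, `actionStatus` and `error` as recorded. The root dataset's
#' `mentions` is extended so the action is discoverable from the crate root.
#'
#' @param crate A crate.
#' @param spec A [run_spec()].
#' @param id Optional explicit action id; default is a generated `#<uuid>`.
#' @return The id of the new `CreateAction`.
#' @export
add_process_run <- function(crate, spec, id = NULL) {
  stopifnot(inherits(spec, "wrroc_run_spec"))
  instr <- resolve(crate, spec$instrument)
  if (is.null(instr))
    stop("instrument not in crate: ", dQuote(spec$instrument), call. = FALSE)
  if (!any(instr$types %in% SOFTWARE_TYPES))
    stop("instrument ", dQuote(spec$instrument),
         " must be typed SoftwareApplication, SoftwareSourceCode or ",
         "ComputationalWorkflow", call. = FALSE)
  for (x in c(spec$inputs, spec$outputs)) require_entity(crate, x, "input/output")
  if (!is.null(spec$agent)) require_entity(crate, spec$agent, "agent")

  if (is.null(id)) id <- new_id(crate, "action")
  props <- list(instrument = ref(spec$instrument))
  if (length(spec$inputs)) props$object <- lapply(spec$inputs, ref)
  if (length(spec$outputs)) props$result <- lapply(spec$outputs, ref)
  if (!is.null(spec$agent)) props$agent <- ref(spec$agent)
  if (!is.null(spec$start)) props$startTime <- spec$start
  if (!is.null(spec$end)) props$endTime <- spec$end
  if (!is.na(spec$status))
    props$actionStatus <- if (spec$status == "Completed") COMPLETED else FAILED
  if (!is.null(spec$error)) props$error <- spec$error
  if (!is.null(spec$description)) props$description <- spec$description
  crate_add_entity(crate, do.call(entity, c(list(id, "CreateAction"), props)))
  mention(crate, id)
  id
}

#' Record a non-file argument value
#'
#' Inputs passed on a command line (numbers, strings) are represented as
#' `PropertyValue` entities with `name` and `value`. Ids follow the
#' deterministic `#<name>-pv` pattern; a second value with the same name gets
#' a numeric suffix rather than silently overwriting the first.
#'
#' @param crate A crate.
#' @param name Parameter-style name of the value.
#' @param value The literal value, stored as given.
#' @return The id of the new `PropertyValue`.
#' @export
add_non_file_value <- function(crate, name, value) {
  if (!is.character(name) || !nzchar(name))
    stop("PropertyValue name must be a non-empty string", call. = FALSE)
  base <- paste0("#", gsub("[^A-Za-z0-9._-]", "-", name), "-pv")
  id <- base
  k <- 1L
  while (!is.null(resolve(crate, id))) {
    k <- k + 1L
    id <- sprintf("%s-%d", base, k)
  }
  crate_add_entity(crate, entity(id, "PropertyValue", name = name, value = value))
  id
}

#' Register the main workflow
#'
#' Adds the workflow entity with the three types required of a main workflow
#' (`File`, `SoftwareSourceCode`, `ComputationalWorkflow`) and points the
#' root dataset's `mainEntity` at it. A crate has exactly one main workflow;
#' adding a second is an error. The builder imposes no file-extension
#' constraint, so an entry-point application source works too.
#'
#' @param crate A crate.
#' @param path Workflow id (usually its file path in the crate).
#' @param language_hint Optional language name (e.g. `"cwl"`); recorded as a
#'   `ComputerLanguage` entity referenced via `programmingLanguage`.
#' @return The workflow entity id.
#' @export
add_workflow <- function(crate, path, language_hint = NULL) {
  if (length(prop_ids(crate_root(crate), "mainEntity")) > 0L)
    stop("crate already has a main workflow", call. = FALSE)
  props <- list()
  if (!is.null(language_hint)) {
    lang_id <- paste0("#", language_hint)
    if (is.null(resolve(crate, lang_id)))
      crate_add_entity(crate, entity(lang_id, "ComputerLanguage",
                                     name = language_hint))
    props$programmingLanguage <- ref(lang_id)
  }
  crate_add_entity(crate, do.call(entity, c(
    list(path, c("File", "SoftwareSourceCode", "ComputationalWorkflow")), props)))
  crate_set_prop(crate, crate$root_id, "mainEntity", ref(path))
  if (!path %in% prop_ids(crate_root(crate), "hasPart"))
    crate_append_prop(crate, crate$root_id, "hasPart", ref(path))
  path
}

#' Declare a formal parameter on a workflow or tool
#'
#' Creates the `FormalParameter` entity and extends the owner's `input` or
#' `output` list. Workflow-level and tool-level parameters are declared the
#' same way; only the owner differs.
#'
#' @param crate A crate.
#' @param owner Id of the owning workflow or tool.
#' @param direction `"input"` or `"output"`.
#' @param spec A [param_spec()].
#' @return The parameter id.
#' @export
add_formal_parameter <- function(crate, owner, direction = c("input", "output"),
                                 spec) {
  direction <- match.arg(direction)
  require_entity(crate, owner, "parameter owner")
  stopifnot(inherits(spec, "wrroc_param_spec"))
  if (!is.null(resolve(crate, spec$id)))
    stop("duplicate parameter id: ", dQuote(spec$id), call. = FALSE)
  props <- list(name = spec$name, additionalType = spec$additional_type)
  if (!is.null(spec$encoding_format)) props$encodingFormat <- spec$encoding_format
  if (!is.null(spec$value_required))
    props$valueRequired <- if (isTRUE(spec$value_required)) "True" else "False"
  crate_add_entity(crate, do.call(entity, c(list(spec$id, "FormalParameter"),
                                            props)))
  crate_append_prop(crate, owner, direction, ref(spec$id))
  spec$id
}

#' Link an actual value to its formal parameter
#'
#' The relationship between an actual value (file, collection or
#' `PropertyValue`) and the formal parameter it realized is expressed through
#' `exampleOfWork` on the value entity. The property is list-valued: one
#' entity may realize several parameters (e.g. a workflow-level and a
#' tool-level slot).
#'
#' @param crate A crate.
#' @param data_entity Id of the value entity.
#' @param parameter Id of the `FormalParameter`.
#' @return `data_entity`, invisibly.
#' @export
link_realization <- function(crate, data_entity, parameter) {
  require_entity(crate, data_entity, "data entity")
  p <- require_entity(crate, parameter, "parameter")
  if (!has_type(p, "FormalParameter"))
    stop(dQuote(parameter), " is not a FormalParameter", call. = FALSE)
  if (identical(data_entity, parameter))
    stop("an entity cannot realize itself", call. = FALSE)
  crate_append_prop(crate, data_entity, "exampleOfWork", ref(parameter))
  invisible(data_entity)
}

#' Declare a workflow step
#'
#' Steps are the prospective side of a provenance crate: the workflow lists
#' `HowToStep`s via `step`, each pointing to the tool it runs via
#' `workExample`; the workflow also aggregates its tools via `hasPart` (two
#' steps running the same tool share one `hasPart` entry). The workflow
#' gains the `HowTo` type when its first step is declared.
#'
#' @param crate A crate.
#' @param workflow Id of the main workflow.
#' @param tool Id of a `SoftwareApplication` in the crate.
#' @param position Zero-based step position; positions must be unique.
#' @param name Optional step name; the id is `<workflow-id>#<name>` (default
#'   `step-<position>`).
#' @return The `HowToStep` id.
#' @export
add_step <- function(crate, workflow, tool, position, name = NULL) {
  wf <- require_entity(crate, workflow, "workflow")
  main <- prop_ids(crate_root(crate), "mainEntity")
  if (!workflow %in% main)
    stop("steps can only be added to the main workflow", call. = FALSE)
  t <- require_entity(crate, tool, "tool")
  if (!has_type(t, "SoftwareApplication"))
    stop("step tool ", dQuote(tool), " must be a SoftwareApplication",
         call. = FALSE)
  for (sid in prop_ids(wf, "step")) {
    s <- resolve(crate, sid)
    if (!is.null(s) && identical(first_literal(s, "position"),
                                 as.character(position)))
      stop("step position ", position, " already used", call. = FALSE)
  }
  if (is.null(name)) name <- sprintf("step-%s", position)
  id <- paste0(workflow, "#", name)
  crate_add_entity(crate, entity(id, "HowToStep",
                                 position = as.character(position),
                                 workExample = ref(tool)))
  crate_append_prop(crate, workflow, "step", ref(id))
  if (!tool %in% prop_ids(wf, "hasPart"))
    crate_append_prop(crate, workflow, "hasPart", ref(tool))
  if (!has_type(wf, "HowTo"))
    crate_set_types(crate, workflow, c(wf$types, "HowTo"))
  id
}

#' Record the execution of a step
#'
#' A step execution is a `ControlAction` pointing to the `HowToStep` via
#' `instrument` and to the tool execution(s) via `object`. A step execution
#' does not coincide with a tool execution: a single step may map to several
#' executions of the same tool (scattering).
#'
#' @param crate A crate.
#' @param step Id of the `HowToStep`.
#' @param actions Non-empty character vector of `CreateAction` ids.
#' @param id Optional explicit id.
#' @return The `ControlAction` id.
#' @export
add_step_execution <- function(crate, step, actions, id = NULL) {
  s <- require_entity(crate, step, "step")
  if (!has_type(s, "HowToStep"))
    stop(dQuote(step), " is not a HowToStep", call. = FALSE)
  if (length(actions) == 0L)
    stop("a step execution needs at least one action", call. = FALSE)
  for (a in actions) {
    ae <- require_entity(crate, a, "action")
    if (!has_type(ae, "CreateAction"))
      stop(dQuote(a), " is not a CreateAction", call. = FALSE)
  }
  if (is.null(id)) id <- new_id(crate, "control")
  crate_add_entity(crate, entity(id, "ControlAction", instrument = ref(step),
                                 object = lapply(actions, ref)))
  mention(crate, id)
  id
}

#' Record the workflow engine execution
#'
#' The run of the workflow management system itself is an `OrganizeAction`:
#' `instrument` points to the WMS, `object` to the step executions (plus an
#' optional configuration file, e.g. a `streamflow.yml`), and `result` to the
#' workflow-level `CreateAction`.
#'
#' @param crate A crate.
#' @param wms Id of the WMS entity.
#' @param steps Character vector of `ControlAction` ids.
#' @param workflow_run Id of the workflow-level `CreateAction`.
#' @param config Optional id of a configuration file entity.
#' @param id Optional explicit id.
#' @return The `OrganizeAction` id.
#' @export
add_engine_run <- function(crate, wms, steps, workflow_run, config = NULL,
                           id = NULL) {
  require_entity(crate, wms, "WMS")
  wr <- resolve(crate, workflow_run)
  if (is.null(wr) || !has_type(wr, "CreateAction"))
    stop("workflow_run must be the workflow-level CreateAction", call. = FALSE)
  objects <- lapply(steps, function(s) {
    require_entity(crate, s, "step execution"); ref(s)
  })
  if (!is.null(config)) {
    require_entity(crate, config, "config file")
    objects <- c(objects, list(ref(config)))
  }
  if (is.null(id)) id <- new_id(crate, "organize")
  props <- list(instrument = ref(wms), result = ref(workflow_run))
  if (length(objects)) props$object <- objects
  crate_add_entity(crate, do.call(entity, c(list(id, "OrganizeAction"), props)))
  mention(crate, id)
  id
}

#' Connect a source parameter to a target parameter
#'
#' Parameter connections document data flow: how workflow-level parameters
#' map onto tool-level parameters, and how one tool's output feeds the next
#' tool's input. The connection is a `ParameterConnection` entity with
#' `sourceParameter` and `targetParameter`, referenced from the relevant step
#' or workflow via `connection`.
#'
#' @param crate A crate.
#' @param holder Id of the `HowToStep` (or the workflow) holding the
#'   connection.
#' @param source,target Ids of the source and target `FormalParameter`s.
#' @param id Optional explicit id.
#' @return The `ParameterConnection` id.
#' @export
add_parameter_connection <- function(crate, holder, source, target, id = NULL) {
  h <- require_entity(crate, holder, "connection holder")
  main <- prop_ids(crate_root(crate), "mainEntity")
  if (!has_type(h, "HowToStep") && !h$id %in% main)
    stop("connection holder must be a HowToStep or the main workflow",
         call. = FALSE)
  if (identical(source, target))
    stop("source and target parameter must differ", call. = FALSE)
  for (p in c(source, target)) {
    pe <- require_entity(crate, p, "parameter")
    if (!has_type(pe, "FormalParameter"))
      stop(dQuote(p), " is not a FormalParameter", call. = FALSE)
  }
  if (is.null(id)) id <- new_id(crate, "connection")
  crate_add_entity(crate, entity(id, "ParameterConnection",
                                 sourceParameter = ref(source),
                                 targetParameter = ref(target)))
  crate_append_prop(crate, holder, "connection", ref(id))
  id
}

#' Group files into a multi-file dataset
#'
#' Datasets made of several files and directories that must travel as one
#' unit (e.g. a MIRAX image: a main file plus a directory of additional data
#' files) are represented by a `Collection` with `hasPart` and, optionally, a
#' distinguished `mainEntity`.
#'
#' @param crate A crate.
#' @param parts Non-empty character vector of part ids (all in the crate).
#' @param main Optional id of the main part; must be one of `parts`.
#' @param id Optional explicit id.
#' @return The `Collection` id.
#' @export
add_collection <- function(crate, parts, main = NULL, id = NULL) {
  if (length(parts) == 0L)
    stop("a collection needs at least one part", call. = FALSE)
  for (p in parts) require_entity(crate, p, "collection part")
  if (!is.null(main) && !main %in% parts)
    stop("main entity must be one of the parts", call. = FALSE)
  if (is.null(id)) id <- new_id(crate, "collection")
  props <- list(hasPart = lapply(parts, ref))
  if (!is.null(main)) props$mainEntity <- ref(main)
  crate_add_entity(crate, do.call(entity, c(list(id, "Collection"), props)))
  mention(crate, id)
  id
}

#' Record an entity's original name
#'
#' Systems that store files under content-derived names (e.g. their SHA1
#' checksum) record the original file name in `alternateName`; re-execution
#' planning restores it, which matters for formats where names carry meaning.
#' Setting it again replaces the prior value.
#'
#' @param crate A crate.
#' @param entity_id Id of the entity to annotate.
#' @param name The original name.
#' @return `entity_id`, invisibly.
#' @export
set_alternate_name <- function(crate, entity_id, name) {
  require_entity(crate, entity_id)
  crate_set_prop(crate, entity_id, "alternateName", name)
  invisible(entity_id)
}

#' Add a plain data entity
#'
#' Convenience wrapper for declaring files, directories and people that the
#' builder operations will reference.
#'
#' @param crate A crate.
#' @param id Entity id (usually a path).
#' @param types Type term(s), e.g. `"File"`, `"Dataset"`, `"Person"`.
#' @param ... Further properties.
#' @param in_root If `TRUE` (default for files), the root dataset's `hasPart`
#'   is extended.
#' @return The entity id.
#' @export
add_data_entity <- function(crate, id, types = "File", ...,
                            in_root = any(types %in% c("File", "Dataset"))) {
  crate_add_entity(crate, entity(id, types, ...))
  if (in_root && !id %in% prop_ids(crate_root(crate), "hasPart"))
    crate_append_prop(crate, crate$root_id, "hasPart", ref(id))
  id
}

#' Declare profile conformance
#'
#' Writes the profile URI(s) onto the root dataset's `conformsTo` (read back
#' by [detect_profiles()], which also accepts declarations on the metadata
#' descriptor).
#'
#' @param crate A crate.
#' @param profile Profile family name: `"process"`, `"workflow"` or
#'   `"provenance"`.
#' @param version Profile version string.
#' @return The profile URI, invisibly.
#' @export
declare_profile <- function(crate, profile = c("process", "workflow",
                                               "provenance"),
                            version = WRROC_PROFILE_VERSION) {
  profile <- match.arg(profile)
  uri <- profile_uri(profile, version)
  if (!uri %in% prop_ids(crate_root(crate), "conformsTo"))
    crate_append_prop(crate, crate$root_id, "conformsTo", ref(uri))
  invisible(uri)
}
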