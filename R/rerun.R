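#' Build a re-execution plan from a recorded run
#'
#' Recovers the (input parameter -> actual value) map of a recorded workflow
#' run by intersecting the workflow's declared `input` parameters with the
#' run action's `object` list through the `exampleOfWork` links. The result
#' is an engine-neutral plan: actually re-executing requires a workflow
#' engine (and usually containers), which is deliberately out of scope —
#' the plan is what a harness would feed to one.
#'
#' For each input parameter the bound value is the unique member of the
#' action's `object` whose `exampleOfWork` includes that parameter.
#' `PropertyValue`s bind as literals, `Collection`s as collections with
#' their `mainEntity` distinguished, anything else as a file. An
#' `alternateName`, when present, is recorded as the restored original file
#' name. A parameter with no realization is an error unless its
#' `valueRequired` is `"False"` (then it is omitted); two candidates for one
#' parameter is an ambiguity error. Action objects with no `exampleOfWork`
#' link at all are surfaced in `unbound_values` rather than guessed by name.
#' Output parameters are never bound; they are listed in `outputs` so a
#' harness can compare produced outputs with the recorded `result` entities.
#' Planning never mutates the crate.
#'
#' @param crate A crate conforming to the workflow profile.
#' @param action Optional id of the run `CreateAction`; defaults to the
#'   unique workflow-run action (the one whose instrument is the main
#'   workflow).
#' @return A `wrroc_rerun_plan`: list with `workflow`, `action`, `bindings`
#'   (named by parameter name), `outputs`, `unbound_values`.
#' @export
rerun_plan <- function(crate, action = NULL) {
  findings <- validate_crate(crate, "workflow")
  must <- findings[findings$severity == "MUST", , drop = FALSE]
  if (nrow(must) > 0L)
    stop("crate does not conform to the workflow profile:\n",
         paste(sprintf("  %s %s", must$rule_id, must$message), collapse = "\n"),
         call. = FALSE)
  wf_id <- main_workflow_id(crate)
  if (is.null(action)) {
    runs <- workflow_run_ids(crate)
    if (length(runs) != 1L)
      stop("expected exactly one workflow-run action, found ", length(runs),
           call. = FALSE)
    action <- runs[[1L]]
  }
  a <- require_entity(crate, action, "action")
  wf <- resolve(crate, wf_id)
  objects <- prop_ids(a, "object")

  bindings <- list()
  for (pid in prop_ids(wf, "input")) {
    p <- resolve(crate, pid)
    pname <- as.character(first_literal(p, "name"))
    candidates <- Filter(function(oid) {
      oe <- resolve(crate, oid)
      !is.null(oe) && pid %in% prop_ids(oe, "exampleOfWork")
    }, objects)
    if (length(candidates) == 0L) {
      required <- !identical(first_literal(p, "valueRequired"), "False")
      if (required)
        stop("unbound required parameter: ", dQuote(pid), call. = FALSE)
      next
    }
    if (length(candidates) > 1L)
      stop("ambiguous binding for parameter ", dQuote(pid), ": ",
           paste(candidates, collapse = ", "), call. = FALSE)
    oid <- candidates[[1L]]
    oe <- resolve(crate, oid)
    b <- list(parameter = pid, source = oid)
    if (has_type(oe, "PropertyValue")) {
      b$kind <- "literal"
      b$value <- as.character(first_literal(oe, "value"))
    } else if (has_type(oe, "Collection")) {
      b$kind <- "collection"
      main <- prop_ids(oe, "mainEntity")
      if (length(main)) b$main <- main[[1L]]
    } else {
      b$kind <- "file"
    }
    alt <- first_literal(oe, "alternateName")
    if (!is.na(alt)) b$name <- as.character(alt)
    bindings[[pname]] <- b
  }

  unbound <- Filter(function(oid) {
    oe <- resolve(crate, oid)
    is.null(oe) || length(prop_ids(oe, "exampleOfWork")) == 0L
  }, objects)

  outputs <- lapply(prop_ids(wf, "output"), function(pid) {
    p <- resolve(crate, pid)
    list(parameter = pid, name = as.character(first_literal(p, "name")))
  })

  structure(list(workflow = wf_id, action = action, bindings = bindings,
                 outputs = outputs, unbound_values = as.character(unbound)),
            class = "wrroc_rerun_plan")
}

#' @export
print.wrroc_rerun_plan <- function(x, ...) {
  cat("rerun plan for", x$workflow, "(action", paste0(x$action, ")"), "\n")
  for (nm in names(x$bindings)) {
    b <- x$bindings[[nm]]
    cat(" ", nm, " <- ",
        if (b$kind == "literal") b$value else b$source,
        " [", b$kind, "]\n", sep = "")
  }
  if (length(x$unbound_values))
    cat(" unbindable values:", paste(x$unbound_values, collapse = ", "), "\n")
  invisible(x)
}

#' Emit or re-read an engine-neutral job document
#'
#' `emit_job_document()` renders a plan as deterministic key-sorted JSON:
#' literal bindings become scalars; files become
#' `{"class": "File", "path": ...}` and collections
#' `{"class": "Collection", "path": ..., "mainEntity": ...}` objects. A
#' restored original name (`alternateName`) replaces the content-derived
#' basename in `path`. The format is meant for hand-conversion to any
#' engine's input format. `parse_job_document()` reads it back;
#' `plan_to_json()`/`plan_from_json()` round-trip the full plan.
#'
#' @param plan A [rerun_plan()] result.
#' @return JSON text.
#' @export
emit_job_document <- function(plan) {
  nms <- names(plan$bindings)
  nms <- if (is.null(nms)) character() else sort(nms, method = "radix")
  doc <- lapply(nms, function(nm) {
    b <- plan$bindings[[nm]]
    if (b$kind == "literal") return(b$value)
    path <- if (!is.null(b$name)) b$name else b$source
    out <- list(class = if (b$kind == "collection") "Collection" else "File",
                path = path)
    if (!is.null(b$main)) out$mainEntity <- b$main
    out
  })
  names(doc) <- nms
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                digits = NA))
}

#' @rdname emit_job_document
#' @param json JSON text from `emit_job_document()`.
#' @export
parse_job_document <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = FALSE)
}

#' @rdname emit_job_document
#' @export
plan_to_json <- function(plan) {
  as.character(jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, pretty = 2,
                                digits = NA, null = "null"))
}

#' @rdname emit_job_document
#' @export
plan_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  x$unbound_values <- as.character(unlist(x$unbound_values))
  structure(x, class = "wrroc_rerun_plan")
}
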