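WRROC_PROFILE_VERSION <- "0.5"
PROFILE_FAMILIES <- c("process", "workflow", "provenance")

profile_uri <- function(name, version = WRROC_PROFILE_VERSION) {
  sprintf("https://w3id.org/ro/wfrun/%s/%s", name, version)
}

DATA_ENTITY_TYPES <- c("File", "MediaObject", "Dataset", "Collection",
                       "PropertyValue", "CreativeWork")

#' Profiles declared by a crate
#'
#' Inspects `conformsTo` on both the root dataset and the metadata
#' descriptor for workflow-run profile URIs
#' (`https://w3id.org/ro/wfrun/<family>/<version>`). Matching is
#' version-tolerant: any 0.x member of a family is recognized, with a note
#' when the version differs from the library's pinned one (0.5).
#'
#' @param crate A crate.
#' @return Data frame with columns `name`, `uri`, `version`, `note` (one row
#'   per declared profile; zero rows when none declared).
#' @export
detect_profiles <- function(crate) {
  uris <- unique(c(prop_ids(crate_root(crate), "conformsTo"),
                   prop_ids(crate_descriptor(crate), "conformsTo")))
  m <- regmatches(uris, regexec(
    "w3id\\.org/ro/wfrun/(process|workflow|provenance)/([0-9][0-9.]*)", uris))
  hit <- lengths(m) == 3L
  name <- vapply(m[hit], `[[`, character(1), 2L)
  version <- vapply(m[hit], `[[`, character(1), 3L)
  note <- ifelse(version == WRROC_PROFILE_VERSION, "",
                 sprintf("declared version %s differs from pinned %s",
                         version, WRROC_PROFILE_VERSION))
  data.frame(name = name, uri = uris[hit], version = version, note = note,
             stringsAsFactors = FALSE)
}

#' Profiles implied by the subset hierarchy
#'
#' Provenance Run Crate is a superset of Workflow Run Crate, which is a
#' superset of Process Run Crate; conformance to a profile implies
#' conformance to everything below it.
#'
#' @param names Character vector of profile family names.
#' @return Character vector including all implied families, ordered
#'   process < workflow < provenance.
#' @export
implied_profiles <- function(names) {
  hi <- max(c(0L, match(names, PROFILE_FAMILIES)), na.rm = TRUE)
  if (hi == 0L) character() else PROFILE_FAMILIES[seq_len(hi)]
}

finding <- function(rule, severity, entity, message) {
  data.frame(rule_id = rule, severity = severity,
             entity = if (is.null(entity)) NA_character_ else entity,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(rule_id = character(), severity = character(),
             entity = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a crate against a run profile
#'
#' Checks the crate against the rule catalog of the requested profile.
#' Because the profiles form a subset hierarchy, validating against
#' `"workflow"` also applies every process-level rule, and `"provenance"`
#' applies all three rule sets. Findings are data, not exceptions: each row
#' names a stable rule id, a MUST/SHOULD severity, the offending entity (or
#' `NA` for crate-level findings) and a message. A crate conforms iff the
#' MUST subset is empty. Validation never mutates the crate.
#'
#' Rule catalog: P1 at least one `CreateAction`; P2 every `CreateAction`'s
#' `instrument` resolves to a software-typed entity; P3 `object`/`result`
#' members are data entities, `PropertyValue`s or `Collection`s (SHOULD);
#' P4 `Collection`s have `hasPart`; W1 the root `mainEntity` is a workflow
#' with types File + SoftwareSourceCode + ComputationalWorkflow; W2 some
#' `CreateAction`'s instrument is the main workflow; W3 referenced formal
#' parameters are typed and named (SHOULD); W4 `exampleOfWork` points from
#' data/value entities to `FormalParameter`s; V1 the workflow's `hasPart`
#' lists every tool referenced by a step's `workExample`; V2 every
#' `ControlAction` instrument is a `HowToStep` of the main workflow; V3 every
#' `ControlAction` `object` member is a `CreateAction`; V4 an
#' `OrganizeAction`'s `result` is the workflow-run action; V5
#' `ParameterConnection`s reference existing `FormalParameter`s; V6
#' `actionStatus` is a recognized term and `error` co-occurs only with
#' failure (SHOULD).
#'
#' @param crate A crate.
#' @param profile `"process"`, `"workflow"` or `"provenance"`.
#' @return A data frame of findings (zero rows when fully conformant),
#'   ordered by rule id then entity, with class `wrroc_findings`.
#' @export
validate_crate <- function(crate, profile = c("process", "workflow",
                                              "provenance")) {
  if (!is.character(profile) || !all(profile %in% PROFILE_FAMILIES))
    stop("unknown profile: ", paste(setdiff(profile, PROFILE_FAMILIES),
                                    collapse = ", "), call. = FALSE)
  profile <- match.arg(profile)
  f <- rules_process(crate)
  if (profile %in% c("workflow", "provenance")) f <- rbind(f, rules_workflow(crate))
  if (profile == "provenance") f <- rbind(f, rules_provenance(crate))
  f <- f[order(f$rule_id, f$entity, f$message, method = "radix"), , drop = FALSE]
  rownames(f) <- NULL
  class(f) <- c("wrroc_findings", class(f))
  f
}

#' @export
print.wrroc_findings <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("no findings\n")
  } else {
    for (i in seq_len(nrow(x)))
      cat(x$severity[i], x$rule_id[i],
          if (is.na(x$entity[i])) "<crate>" else x$entity[i],
          x$message[i], "\n")
  }
  invisible(x)
}

#' @rdname validate_crate
#' @param findings A findings data frame.
#' @export
is_conformant <- function(findings) !any(findings$severity == "MUST")

main_workflow_id <- function(crate) {
  m <- prop_ids(crate_root(crate), "mainEntity")
  if (length(m)) m[[1L]] else NA_character_
}

workflow_run_ids <- function(crate) {
  main <- main_workflow_id(crate)
  if (is.na(main)) return(character())
  ids <- character()
  for (a in entities_of_type(crate, "CreateAction"))
    if (main %in% prop_ids(a, "instrument")) ids <- c(ids, a$id)
  ids
}

rules_process <- function(crate) {
  f <- no_findings()
  actions <- entities_of_type(crate, "CreateAction")
  if (length(actions) == 0L)
    f <- rbind(f, finding("P1", "MUST", NULL, "no CreateAction in crate"))
  for (a in actions) {
    instr <- prop_ids(a, "instrument")
    ok <- length(instr) > 0L
    if (ok) {
      ie <- resolve(crate, instr[[1L]])
      ok <- !is.null(ie) && any(ie$types %in% SOFTWARE_TYPES)
    }
    if (!ok)
      f <- rbind(f, finding("P2", "MUST", a$id,
                            "instrument missing or not a software-typed entity"))
    for (nm in c("object", "result")) {
      for (oid in prop_ids(a, nm)) {
        oe <- resolve(crate, oid)
        if (!is.null(oe) && !any(oe$types %in% DATA_ENTITY_TYPES))
          f <- rbind(f, finding("P3", "SHOULD", a$id,
                                sprintf("%s member %s is not a data entity, PropertyValue or Collection",
                                        nm, oid)))
      }
    }
  }
  for (cl in entities_of_type(crate, "Collection")) {
    if (length(prop_ids(cl, "hasPart")) == 0L)
      f <- rbind(f, finding("P4", "MUST", cl$id, "Collection without hasPart"))
  }
  f
}

rules_workflow <- function(crate) {
  f <- no_findings()
  main <- main_workflow_id(crate)
  wf <- if (!is.na(main)) resolve(crate, main) else NULL
  need <- c("File", "SoftwareSourceCode", "ComputationalWorkflow")
  if (is.null(wf) || !all(need %in% wf$types))
    f <- rbind(f, finding("W1", "MUST", if (is.null(wf)) NULL else wf$id,
                          "root mainEntity is not a workflow typed File + SoftwareSourceCode + ComputationalWorkflow"))
  if (!is.null(wf) && length(workflow_run_ids(crate)) == 0L)
    f <- rbind(f, finding("W2", "MUST", NULL,
                          "no CreateAction has the main workflow as instrument"))
  for (owner in crate$graph) {
    for (nm in c("input", "output")) {
      for (pid in prop_ids(owner, nm)) {
        p <- resolve(crate, pid)
        if (is.null(p) || !has_type(p, "FormalParameter") ||
            !nzchar(as.character(first_literal(p, "name") %||% "")) ||
            is.na(first_literal(p, "name")))
          f <- rbind(f, finding("W3", "SHOULD", owner$id,
                                sprintf("%s member %s is not a named FormalParameter",
                                        nm, pid)))
      }
    }
    for (pid in prop_ids(owner, "exampleOfWork")) {
      p <- resolve(crate, pid)
      if (is.null(p) || !has_type(p, "FormalParameter"))
        f <- rbind(f, finding("W4", "MUST", owner$id,
                              sprintf("exampleOfWork target %s is not a FormalParameter",
                                      pid)))
    }
  }
  f
}

rules_provenance <- function(crate) {
  f <- no_findings()
  main <- main_workflow_id(crate)
  wf <- if (!is.na(main)) resolve(crate, main) else NULL
  step_ids <- if (is.null(wf)) character() else prop_ids(wf, "step")
  if (!is.null(wf)) {
    parts <- prop_ids(wf, "hasPart")
    for (sid in step_ids) {
      s <- resolve(crate, sid)
      if (is.null(s)) next
      for (tid in prop_ids(s, "workExample")) {
        if (!tid %in% parts)
          f <- rbind(f, finding("V1", "MUST", wf$id,
                                sprintf("tool %s referenced by step %s missing from workflow hasPart",
                                        tid, sid)))
      }
    }
  }
  for (ca in entities_of_type(crate, "ControlAction")) {
    instr <- prop_ids(ca, "instrument")
    s <- if (length(instr)) resolve(crate, instr[[1L]]) else NULL
    if (is.null(s) || !has_type(s, "HowToStep") || !instr[[1L]] %in% step_ids)
      f <- rbind(f, finding("V2", "MUST", ca$id,
                            "instrument is not a HowToStep of the main workflow"))
    for (oid in prop_ids(ca, "object")) {
      oe <- resolve(crate, oid)
      if (is.null(oe) || !has_type(oe, "CreateAction"))
        f <- rbind(f, finding("V3", "MUST", ca$id,
                              sprintf("object member %s is not a CreateAction", oid)))
    }
  }
  wf_runs <- workflow_run_ids(crate)
  for (oa in entities_of_type(crate, "OrganizeAction")) {
    res <- prop_ids(oa, "result")
    if (length(res) == 0L || !res[[1L]] %in% wf_runs)
      f <- rbind(f, finding("V4", "MUST", oa$id,
                            "result is not the workflow-run CreateAction"))
  }
  for (pc in entities_of_type(crate, "ParameterConnection")) {
    for (nm in c("sourceParameter", "targetParameter")) {
      pid <- prop_ids(pc, nm)
      p <- if (length(pid)) resolve(crate, pid[[1L]]) else NULL
      if (is.null(p) || !has_type(p, "FormalParameter"))
        f <- rbind(f, finding("V5", "MUST", pc$id,
                              sprintf("%s does not reference an existing FormalParameter", nm)))
    }
  }
  for (a in c(entities_of_type(crate, "CreateAction"),
              entities_of_type(crate, "OrganizeAction"))) {
    st <- prop_values(a, "actionStatus")
    status <- if (length(st) && !is_ref(st[[1L]])) st[[1L]] else
      if (length(st)) st[[1L]]$id else NULL
    known <- c(COMPLETED, FAILED, "ActiveActionStatus", "PotentialActionStatus",
               paste0("http://schema.org/", c(COMPLETED, FAILED)),
               paste0("https://schema.org/", c(COMPLETED, FAILED)))
    if (!is.null(status) && !status %in% known)
      f <- rbind(f, finding("V6", "SHOULD", a$id,
                            sprintf("unrecognized actionStatus %s", status)))
    has_error <- length(prop_values(a, "error")) > 0L
    failed <- !is.null(status) && grepl("FailedActionStatus", status)
    if (has_error && !failed)
      f <- rbind(f, finding("V6", "SHOULD", a$id,
                            "error set on an action that did not fail"))
  }
  f
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Mutation catalog for the validator
#'
#' One mutation per validator rule: each entry perturbs a single aspect of a
#' conformant fixture crate and must trigger exactly its paired rule, with
#' only the mutated entity (or the crate level) flagged. Used as a
#' completeness harness for the rule catalog.
#'
#' @return A list of entries with fields `rule_id`, `profile` (the profile to
#'   validate against), `target` (a description of the flagged entity) and
#'   `mutate` (a function taking and returning a crate).
#' @export
mutation_catalog <- function() {
  list(
    list(rule_id = "P1", profile = "process", target = NA_character_,
         mutate = function(cr) {
           for (a in entities_of_type(cr, "CreateAction"))
             crate_remove_entity(cr, a$id)
           cr
         }),
    list(rule_id = "P2", profile = "process",
         target = "#30a65cba-1b75-47dc-ad47-1d33819cf156",
         mutate = function(cr) {
           e <- resolve(cr, "#30a65cba-1b75-47dc-ad47-1d33819cf156")
           e$props[["instrument"]] <- NULL
           crate_add_entity(cr, e, replace = TRUE)
           cr
         }),
    list(rule_id = "P3", profile = "process",
         target = "#30a65cba-1b75-47dc-ad47-1d33819cf156",
         mutate = function(cr) {
           crate_append_prop(cr, "#30a65cba-1b75-47dc-ad47-1d33819cf156",
                             "object", ref("#streamflow"))
           cr
         }),
    list(rule_id = "P4", profile = "process",
         target = "#af0253d688f3409a2c6d24bf6b35df7c4e271292",
         mutate = function(cr) {
           e <- resolve(cr, "#af0253d688f3409a2c6d24bf6b35df7c4e271292")
           e$props[["hasPart"]] <- NULL
           crate_add_entity(cr, e, replace = TRUE)
           cr
         }),
    list(rule_id = "W1", profile = "workflow", target = "predictions.cwl",
         mutate = function(cr) {
           wf <- resolve(cr, "predictions.cwl")
           crate_set_types(cr, "predictions.cwl",
                           setdiff(wf$types, "ComputationalWorkflow"))
           cr
         }),
    list(rule_id = "W2", profile = "workflow", target = NA_character_,
         mutate = function(cr) {
           crate_set_prop(cr, "#30a65cba-1b75-47dc-ad47-1d33819cf156",
                          "instrument", ref("extract_tissue.cwl"))
           cr
         }),
    list(rule_id = "W3", profile = "workflow", target = "predictions.cwl",
         mutate = function(cr) {
           e <- resolve(cr, "predictions.cwl#slide")
           e$props[["name"]] <- NULL
           crate_add_entity(cr, e, replace = TRUE)
           cr
         }),
    list(rule_id = "W4", profile = "workflow",
         target = "final-annotations.tsv",
         fixture = "annotation",
         mutate = function(cr) {
           crate_set_prop(cr, "final-annotations.tsv", "exampleOfWork",
                          ref("./"))
           cr
         }),
    list(rule_id = "V1", profile = "provenance", target = "predictions.cwl",
         mutate = function(cr) {
           wf <- resolve(cr, "predictions.cwl")
           keep <- Filter(function(v) !is_ref(v) || v$id != "classify_tumor.cwl",
                          prop_values(wf, "hasPart"))
           crate_set_prop(cr, "predictions.cwl", "hasPart", keep)
           cr
         }),
    list(rule_id = "V2", profile = "provenance", target = "#control-0001",
         mutate = function(cr) {
           crate_set_prop(cr, "#control-0001", "instrument",
                          ref("extract_tissue.cwl"))
           cr
         }),
    list(rule_id = "V3", profile = "provenance", target = "#control-0001",
         mutate = function(cr) {
           crate_append_prop(cr, "#control-0001", "object",
                             ref("streamflow.yml"))
           cr
         }),
    list(rule_id = "V4", profile = "provenance", target = "#organize-0001",
         mutate = function(cr) {
           crate_set_prop(cr, "#organize-0001", "result",
                          ref("#457c80d0-75e8-46d6-bada-b3fe82ea0ef1"))
           cr
         }),
    list(rule_id = "V5", profile = "provenance", target = "#connection-0001",
         mutate = function(cr) {
           crate_set_prop(cr, "#connection-0001", "targetParameter",
                          ref("#no-such-parameter"))
           cr
         }),
    list(rule_id = "V6", profile = "provenance",
         target = "#457c80d0-75e8-46d6-bada-b3fe82ea0ef1",
         mutate = function(cr) {
           crate_set_prop(cr, "#457c80d0-75e8-46d6-bada-b3fe82ea0ef1",
                          "error", "synthetic failure message")
           cr
         })
  )
}
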