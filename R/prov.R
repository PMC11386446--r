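PROV_NS <- "http://www.w3.org/ns/prov#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"
CRATE_BASE <- "arcp://wrroc/"

#' Crate-to-PROV term mapping
#'
#' The correspondence between run-crate vocabulary and PROV-O, with the SKOS
#' relation strength of each pair (`exact`, `close`, `broader`, `related`).
#' Only `exact`, `close` and `broader` rows generate statements on export;
#' `related` rows (e.g. `SoftwareApplication` vs `prov:SoftwareAgent`, or
#' `agent` vs `wasStartedBy`/`wasEndedBy`) are carried as annotations so
#' consumers can filter by mapping strength.
#'
#' @return Data frame with columns `term`, `relation`, `prov`, `exported`.
#' @export
mapping_table <- function() {
  m <- rbind(
    c("Action",                "close",   "Activity",                TRUE),
    c("CreateAction",          "broader", "Activity",                TRUE),
    c("OrganizeAction",        "broader", "Activity",                TRUE),
    c("Person",                "exact",   "Person",                  TRUE),
    c("Organization",          "exact",   "Organization",            TRUE),
    c("SoftwareApplication",   "related", "SoftwareAgent",           FALSE),
    c("ComputationalWorkflow", "broader", "Plan, Entity",            TRUE),
    c("HowTo",                 "broader", "Plan, Entity",            TRUE),
    c("MediaObject",           "broader", "Entity",                  TRUE),
    c("Dataset",               "broader", "Entity",                  TRUE),
    c("PropertyValue",         "broader", "Entity",                  TRUE),
    c("startTime",             "close",   "startedAtTime",           TRUE),
    c("endTime",               "close",   "endedAtTime",             TRUE),
    c("agent",                 "related", "wasStartedBy, wasEndedBy", FALSE),
    c("agent+instrument",      "broader", "wasAssociatedWith",       TRUE),
    c("instrument",            "related", "hadPlan on Association",  TRUE),
    c("object",                "exact",   "used",                    TRUE),
    c("result",                "close",   "wasGeneratedBy",          TRUE)
  )
  data.frame(term = m[, 1], relation = m[, 2], prov = m[, 3],
             exported = as.logical(m[, 4]), stringsAsFactors = FALSE)
}

#' @rdname mapping_table
#' @param term A crate term, e.g. `"object"`.
#' @return `lookup_mapping()`: the matching row(s), zero rows when the term
#'   is unmapped.
#' @export
lookup_mapping <- function(term) {
  m <- mapping_table()
  m[m$term == term, , drop = FALSE]
}

crate_iri <- function(id) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", id) || grepl("^urn:", id))
    return(id)
  paste0(CRATE_BASE, utils::URLencode(id))
}

prov_statement <- function(subject, predicate, object, kind = "iri",
                           datatype = NA_character_) {
  data.frame(subject = subject, predicate = predicate, object = object,
             kind = kind, datatype = datatype, stringsAsFactors = FALSE)
}

PLAN_TYPES <- c("ComputationalWorkflow", "HowTo", "HowToStep",
                "SoftwareApplication", "SoftwareSourceCode")

#' Export a crate's run description to W3C PROV
#'
#' Maps the retrospective provenance of a crate to PROV-O statements:
#' actions become `prov:Activity`; action inputs become `prov:used` edges
#' and outputs inverse `prov:wasGeneratedBy` edges; agents become
#' `prov:wasAssociatedWith` targets typed `prov:Person`/`prov:Organization`;
#' when an action has both an agent and an instrument, a qualified
#' `prov:Association` node carrying `prov:hadPlan` to the instrument is
#' generated (node ids derive deterministically from the action id);
#' workflows, tools and steps are typed both `prov:Plan` and `prov:Entity`;
#' data values are typed `prov:Entity`; start/end times become
#' `prov:startedAtTime`/`prov:endedAtTime` (typed `xsd:dateTime` when
#' parseable, plain literals otherwise).
#'
#' The `object` of an `OrganizeAction` may mix step executions
#' (`ControlAction`s) and configuration files: activities cannot be `used`
#' in PROV, so only non-action objects are exported and each skipped
#' action-to-action link is recorded in the result's `annotations`
#' attribute, along with the `related`-strength mapping rows that are never
#' exported as triples.
#'
#' @param crate A crate; must conform to at least the process profile
#'   (blocking MUST findings make the export fail with a message listing
#'   them).
#' @return Data frame of statements (columns `subject`, `predicate`,
#'   `object`, `kind`, `datatype`), classed `wrroc_prov`, sorted
#'   deterministically, with an `annotations` attribute.
#' @export
to_prov <- function(crate) {
  findings <- validate_crate(crate, "process")
  must <- findings[findings$severity == "MUST", , drop = FALSE]
  if (nrow(must) > 0L)
    stop("crate does not conform to the process profile:\n",
         paste(sprintf("  %s %s %s", must$rule_id,
                       ifelse(is.na(must$entity), "<crate>", must$entity),
                       must$message), collapse = "\n"),
         call. = FALSE)

  st <- list()
  notes <- character()
  add <- function(...) st[[length(st) + 1L]] <<- prov_statement(...)
  typed_entity <- new.env(parent = emptyenv())
  type_once <- function(id, prov_types) {
    key <- paste(id, paste(prov_types, collapse = ","))
    if (is.null(typed_entity[[key]])) {
      typed_entity[[key]] <- TRUE
      for (tp in prov_types)
        add(crate_iri(id), RDF_TYPE, paste0(PROV_NS, tp))
    }
  }

  actions <- c(entities_of_type(crate, "CreateAction"),
               entities_of_type(crate, "OrganizeAction"))
  for (a in actions) {
    add(crate_iri(a$id), RDF_TYPE, paste0(PROV_NS, "Activity"))
    for (oid in prop_ids(a, "object")) {
      oe <- resolve(crate, oid)
      if (!is.null(oe) && (has_type(oe, "ControlAction") ||
                           has_type(oe, "CreateAction") ||
                           has_type(oe, "OrganizeAction"))) {
        notes <- c(notes, sprintf(
          "omitted action-to-action object link %s -> %s (no PROV mapping)",
          a$id, oid))
        next
      }
      add(crate_iri(a$id), paste0(PROV_NS, "used"), crate_iri(oid))
      if (!is.null(oe)) type_once(oid, "Entity")
    }
    for (rid in prop_ids(a, "result")) {
      re <- resolve(crate, rid)
      if (!is.null(re) && (has_type(re, "ControlAction") ||
                           has_type(re, "CreateAction"))) next
      add(crate_iri(rid), paste0(PROV_NS, "wasGeneratedBy"), crate_iri(a$id))
      if (!is.null(re)) type_once(rid, "Entity")
    }
    agent <- prop_ids(a, "agent")
    instr <- prop_ids(a, "instrument")
    if (length(agent)) {
      g <- resolve(crate, agent[[1L]])
      add(crate_iri(a$id), paste0(PROV_NS, "wasAssociatedWith"),
          crate_iri(agent[[1L]]))
      if (!is.null(g)) {
        if (has_type(g, "Person")) type_once(agent[[1L]], "Person")
        if (has_type(g, "Organization")) type_once(agent[[1L]], "Organization")
      }
      if (length(instr)) {
        assoc <- paste0("urn:wrroc:association:",
                        utils::URLencode(sub("^#", "", a$id), reserved = TRUE))
        add(crate_iri(a$id), paste0(PROV_NS, "qualifiedAssociation"), assoc)
        add(assoc, RDF_TYPE, paste0(PROV_NS, "Association"))
        add(assoc, paste0(PROV_NS, "hadPlan"), crate_iri(instr[[1L]]))
      }
    }
    times <- c(startTime = "startedAtTime", endTime = "endedAtTime")
    for (crate_term in names(times)) {
      v <- first_literal(a, crate_term)
      if (!is.na(v))
        add(crate_iri(a$id), paste0(PROV_NS, times[[crate_term]]),
            as.character(v), kind = "literal",
            datatype = if (!is.na(parse_time(v))) XSD_DATETIME
                       else NA_character_)
    }
  }
  for (e in crate$graph) {
    if (any(e$types %in% PLAN_TYPES) && !has_type(e, "CreateAction"))
      type_once(e$id, c("Plan", "Entity"))
  }
  rel <- mapping_table()
  rel <- rel[!rel$exported, , drop = FALSE]
  notes <- c(notes, sprintf("related-match mapping not exported: %s ~ %s",
                            rel$term, rel$prov))

  out <- do.call(rbind, st)
  out <- unique(out)
  out <- out[order(out$subject, out$predicate, out$object, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotations") <- notes
  class(out) <- c("wrroc_prov", class(out))
  out
}

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

#' Serialize PROV statements
#'
#' `as_ntriples()` emits one statement per line (deterministically sorted by
#' [to_prov()]); `as_provn()` emits a compact PROV-N subset (`activity`,
#' `used`, `wasGeneratedBy`, `wasAssociatedWith`, `hadPlan` via qualified
#' association, and type attributes).
#'
#' @param prov A [to_prov()] result.
#' @return Character scalar.
#' @export
as_ntriples <- function(prov) {
  lines <- vapply(seq_len(nrow(prov)), function(i) {
    obj <- if (prov$kind[i] == "literal") {
      lit <- paste0("\"", nt_escape(prov$object[i]), "\"")
      if (!is.na(prov$datatype[i]))
        lit <- paste0(lit, "^^<", prov$datatype[i], ">")
      lit
    } else paste0("<", prov$object[i], ">")
    paste0("<", prov$subject[i], "> <", prov$predicate[i], "> ", obj, " .")
  }, character(1))
  paste(lines, collapse = "\n")
}

#' @rdname as_ntriples
#' @export
as_provn <- function(prov) {
  short <- function(x) {
    x <- sub(PROV_NS, "prov:", x, fixed = TRUE)
    x <- sub(RDF_TYPE, "rdf:type", x, fixed = TRUE)
    if (grepl("^(prov:|rdf:)", x)) x else paste0("<", x, ">")
  }
  body <- vapply(seq_len(nrow(prov)), function(i) {
    s <- short(prov$subject[i]); p <- short(prov$predicate[i])
    o <- if (prov$kind[i] == "literal")
      paste0("\"", nt_escape(prov$object[i]), "\"")
    else short(prov$object[i])
    if (p == "rdf:type") sprintf("  entity(%s, [prov:type = '%s'])", s, o)
    else sprintf("  %s(%s, %s)", sub("^prov:", "", p), s, o)
  }, character(1))
  paste(c("document",
          paste0("  prefix prov <", PROV_NS, ">"),
          body, "endDocument"), collapse = "\n")
}

#' @export
print.wrroc_prov <- function(x, ...) {
  cat(nrow(x), "PROV statements\n")
  cat(as_ntriples(utils::head(x, 10L)), "\n")
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
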