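#' @importFrom jsonlite fromJSON toJSON
NULL

RO_CRATE_CONTEXT <- "https://w3id.org/ro/crate/1.1/context"
WFRUN_TERMS <- "https://w3id.org/ro/terms/workflow-run"
METADATA_IDS <- c("ro-crate-metadata.json", "ro-crate-metadata.jsonld")

#' Create an empty RO-Crate
#'
#' Builds an in-memory crate with the metadata descriptor and root dataset,
#' mutually linked via `about`. The crate is an environment, so builder
#' operations modify it in place and can return the ids of the entities they
#' create.
#'
#' @param name Optional name for the root dataset.
#' @param context The `@context` to keep verbatim; defaults to the RO-Crate
#'   1.1 context URL plus the workflow-run term set URL.
#' @param deterministic_ids If `TRUE`, generated entity ids follow the
#'   reproducible `#action-0001` pattern instead of `#`-prefixed v4 UUIDs.
#' @return An object of class `wrroc_crate`.
#' @examples
#' crate <- new_crate(name = "demo")
#' crate_root(crate)$id
#' @export
new_crate <- function(name = NULL, context = list(RO_CRATE_CONTEXT, WFRUN_TERMS),
                      deterministic_ids = FALSE) {
  crate <- new.env(parent = emptyenv())
  class(crate) <- "wrroc_crate"
  crate$graph <- list()
  crate$context <- context
  crate$descriptor_id <- "ro-crate-metadata.json"
  crate$root_id <- "./"
  crate$notes <- character()
  crate$deterministic_ids <- isTRUE(deterministic_ids)
  crate$id_counter <- 0L
  root_props <- list(datePublished = "2024-01-01", description = "wrroc:synthetic")
  if (!is.null(name)) root_props$name <- name
  crate_add_entity(crate, entity("ro-crate-metadata.json", "CreativeWork",
                                 about = ref("./"),
                                 conformsTo = ref("https://w3id.org/ro/crate/1.1")))
  crate_add_entity(crate, do.call(entity, c(list("./", "Dataset"), root_props)))
  crate
}

#' @export
print.wrroc_crate <- function(x, ...) {
  profs <- detect_profiles(x)
  cat("<wrroc_crate> ", length(x$graph), " entities",
      if (nrow(profs)) paste0("; profiles: ",
                              paste(profs$name, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Low-level crate accessors
#'
#' `crate_root()` and `crate_descriptor()` return the root dataset and the
#' metadata descriptor entity; `crate_ids()` the ids of all graph nodes in
#' insertion order.
#'
#' @param crate A [new_crate()] object.
#' @return An entity, or a character vector for `crate_ids()`.
#' @export
crate_root <- function(crate) crate$graph[[crate$root_id]]

#' @rdname crate_root
#' @export
crate_descriptor <- function(crate) crate$graph[[crate$descriptor_id]]

#' @rdname crate_root
#' @export
crate_ids <- function(crate) names(crate$graph)

#' Add or replace entities and properties
#'
#' Internal-flavoured helpers used by the builder layer; exposed because
#' fixtures and advanced callers need direct graph edits.
#' `crate_add_entity()` refuses duplicate ids unless `replace = TRUE`.
#' `crate_set_prop()` replaces a property wholesale; `crate_append_prop()`
#' appends values to it; `crate_set_types()` replaces the type set.
#'
#' @param crate A crate.
#' @param e An [entity()].
#' @param replace Allow overwriting an existing entity with the same id.
#' @return The entity id, invisibly.
#' @export
crate_add_entity <- function(crate, e, replace = FALSE) {
  stopifnot(inherits(e, "wrroc_entity"))
  if (!replace && !is.null(crate$graph[[e$id]]))
    stop("duplicate @id in graph: ", dQuote(e$id), call. = FALSE)
  crate$graph[[e$id]] <- e
  invisible(e$id)
}

#' @rdname crate_add_entity
#' @param id Entity id to modify.
#' @param name Property name.
#' @param values New value(s) (literal, [ref()], or list of these).
#' @export
crate_set_prop <- function(crate, id, name, values) {
  e <- resolve(crate, id)
  if (is.null(e)) stop("no such entity: ", dQuote(id), call. = FALSE)
  e$props[[name]] <- normalize_value(values)
  crate$graph[[id]] <- e
  invisible(id)
}

#' @rdname crate_add_entity
#' @export
crate_append_prop <- function(crate, id, name, values) {
  e <- resolve(crate, id)
  if (is.null(e)) stop("no such entity: ", dQuote(id), call. = FALSE)
  e$props[[name]] <- c(prop_values(e, name), normalize_value(values))
  crate$graph[[id]] <- e
  invisible(id)
}

#' @rdname crate_add_entity
#' @param types Character vector of type terms.
#' @export
crate_set_types <- function(crate, id, types) {
  e <- resolve(crate, id)
  if (is.null(e)) stop("no such entity: ", dQuote(id), call. = FALSE)
  e$types <- as.character(types)
  crate$graph[[id]] <- e
  invisible(id)
}

#' @rdname crate_add_entity
#' @export
crate_remove_entity <- function(crate, id) {
  crate$graph[[id]] <- NULL
  invisible(id)
}

new_id <- function(crate, prefix = "action") {
  if (crate$deterministic_ids) {
    repeat {
      crate$id_counter <- crate$id_counter + 1L
      id <- sprintf("#%s-%04d", prefix, crate$id_counter)
      if (is.null(crate$graph[[id]])) return(id)
    }
  }
  paste0("#", random_uuid())
}

random_uuid <- function() {
  # v4-format UUID from R's RNG (no external uuid dependency)
  hex <- function(n) paste(sprintf("%x", sample(0:15, n, replace = TRUE)),
                           collapse = "")
  paste0(hex(8), "-", hex(4), "-4", hex(3), "-",
         sprintf("%x", sample(8:11, 1)), hex(3), "-", hex(12))
}

#' Look up an entity by id
#'
#' Exact string match on the id; no URI normalization is applied. Returns
#' `NULL` (a distinct not-found signal, not an error) when the id does not
#' resolve inside the graph.
#'
#' @param crate A crate.
#' @param id Entity id.
#' @return The entity, or `NULL`.
#' @export
resolve <- function(crate, id) {
  if (is_ref(id)) id <- id$id
  crate$graph[[id]]
}

#' Entities of a given type
#'
#' Returns, in graph insertion order, every entity whose type set contains
#' `type`.
#'
#' @param crate A crate.
#' @param type Type term, e.g. `"CreateAction"`.
#' @return List of entities.
#' @export
entities_of_type <- function(crate, type) {
  Filter(function(e) has_type(e, type), crate$graph)
}

#' Unresolvable references in a crate
#'
#' Scans every property of every entity and reports reference targets that do
#' not resolve inside the graph. External URIs (anything with a URI scheme,
#' e.g. `https://` data entities or profile URIs) are legal targets: they are
#' reported with `external = TRUE` rather than rejected.
#'
#' @param crate A crate.
#' @return A data frame with columns `from`, `property`, `to`, `external`.
#' @export
dangling_refs <- function(crate) {
  from <- character(); property <- character(); to <- character()
  for (e in crate$graph) {
    for (nm in names(e$props)) {
      for (v in e$props[[nm]]) {
        if (is_ref(v) && is.null(crate$graph[[v$id]])) {
          from <- c(from, e$id); property <- c(property, nm); to <- c(to, v$id)
        }
      }
    }
  }
  data.frame(from = from, property = property, to = to,
             external = grepl("^[A-Za-z][A-Za-z0-9+.-]*://", to),
             stringsAsFactors = FALSE)
}

# ---- reading ----------------------------------------------------------------

#' Read an RO-Crate metadata document
#'
#' Parses the flattened JSON-LD form: a JSON object with `@context` and a
#' flat `@graph` of entities. Single-valued properties are normalized to
#' lists; literals are kept exactly as parsed (strings that look numeric,
#' such as `"14784"`, stay strings). The `@context` is kept verbatim; an
#' unrecognized context is recorded as a note, not an error.
#'
#' @param x JSON text, a path to a `ro-crate-metadata.json` file, or a crate
#'   directory containing one.
#' @return A `wrroc_crate`.
#' @export
read_crate <- function(x) {
  txt <- x
  if (length(x) == 1L && !grepl("{", x, fixed = TRUE)) {
    path <- x
    if (dir.exists(path)) path <- file.path(path, "ro-crate-metadata.json")
    if (!file.exists(path)) stop("no such file: ", dQuote(path), call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
  } else if (length(x) > 1L) {
    txt <- paste(x, collapse = "\n")
  }
  doc <- tryCatch(fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("not valid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(doc[["@graph"]]))
    stop("parse error: document has no @graph", call. = FALSE)
  if (is.null(doc[["@context"]]))
    stop("parse error: document has no @context", call. = FALSE)

  crate <- new.env(parent = emptyenv())
  class(crate) <- "wrroc_crate"
  crate$graph <- list()
  crate$context <- doc[["@context"]]
  crate$notes <- character()
  crate$deterministic_ids <- FALSE
  crate$id_counter <- 0L
  if (!context_recognized(crate$context))
    crate$notes <- c(crate$notes, "unrecognized @context kept verbatim")

  for (node in doc[["@graph"]]) {
    e <- node_to_entity(node)
    if (!is.null(crate$graph[[e$id]]))
      stop("structural error: duplicate @id in @graph: ", dQuote(e$id),
           call. = FALSE)
    crate$graph[[e$id]] <- e
  }

  desc_id <- METADATA_IDS[METADATA_IDS %in% names(crate$graph)]
  if (length(desc_id) == 0L)
    stop("structural error: missing metadata descriptor (ro-crate-metadata.json)",
         call. = FALSE)
  crate$descriptor_id <- desc_id[[1L]]
  about <- prop_ids(crate$graph[[crate$descriptor_id]], "about")
  if (length(about) == 0L || is.null(crate$graph[[about[[1L]]]]))
    stop("structural error: missing root dataset (descriptor `about` target)",
         call. = FALSE)
  crate$root_id <- about[[1L]]
  crate
}

context_recognized <- function(ctx) {
  flat <- unlist(ctx)
  any(grepl("w3id.org/ro/crate", flat, fixed = TRUE))
}

node_to_entity <- function(node) {
  id <- node[["@id"]]
  if (is.null(id)) stop("structural error: graph node without @id", call. = FALSE)
  types <- node[["@type"]]
  if (is.null(types) || length(types) == 0L)
    stop("structural error: entity ", dQuote(id), " has no @type", call. = FALSE)
  types <- unlist(types, use.names = FALSE)
  props <- node[setdiff(names(node), c("@id", "@type"))]
  props <- lapply(props, json_to_values)
  structure(list(id = id, types = as.character(types),
                 props = lapply(props, normalize_value)),
            class = "wrroc_entity")
}

json_to_values <- function(v) {
  if (is.list(v)) {
    if (!is.null(names(v)) && identical(names(v), "@id")) return(ref(v[["@id"]]))
    if (!is.null(names(v)) && "@id" %in% names(v)) return(ref(v[["@id"]]))
    return(lapply(v, json_to_values))
  }
  v
}

# ---- writing ----------------------------------------------------------------

#' Write an RO-Crate metadata document
#'
#' Deterministic serialization: the metadata descriptor first, the root
#' dataset second, remaining entities sorted by id; within an entity the keys
#' are ordered `@id`, `@type`, then alphabetically. References are emitted as
#' `{"@id": ...}` objects; one-element value lists are written as single
#' values. Two writes of the same crate are byte-identical, and
#' `read_crate(write_crate(x))` preserves the graph exactly.
#'
#' @param crate A crate.
#' @param path Optional output path (a file, or a directory to hold
#'   `ro-crate-metadata.json`).
#' @return JSON text, invisibly when `path` is given.
#' @export
write_crate <- function(crate, path = NULL) {
  ids <- names(crate$graph)
  rest <- sort(setdiff(ids, c(crate$descriptor_id, crate$root_id)),
               method = "radix")
  ordered <- c(crate$descriptor_id, crate$root_id, rest)
  graph <- lapply(ordered, function(id) entity_to_json(crate$graph[[id]]))
  doc <- list("@context" = crate$context, "@graph" = graph)
  txt <- as.character(toJSON(doc, auto_unbox = TRUE, pretty = 4, digits = NA,
                             null = "null"))
  if (!is.null(path)) {
    if (dir.exists(path)) path <- file.path(path, "ro-crate-metadata.json")
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

entity_to_json <- function(e) {
  out <- list("@id" = e$id)
  out[["@type"]] <- if (length(e$types) == 1L) e$types[[1L]] else as.list(e$types)
  for (nm in sort(names(e$props), method = "radix")) {
    vals <- lapply(e$props[[nm]], function(v) {
      if (is_ref(v)) list("@id" = v$id) else v
    })
    out[[nm]] <- if (length(vals) == 1L) vals[[1L]] else vals
  }
  out
}

# ---- comparison -------------------------------------------------------------

#' Canonical form and graph equality
#'
#' `crate_canonical()` reduces a crate to a plain nested list (ids, types,
#' alphabetically ordered properties) suitable for `identical()` comparison;
#' `crate_equal()` compares two crates on entity set, types and properties,
#' ignoring key order.
#'
#' @param crate,a,b Crates.
#' @return A list, or a logical scalar.
#' @export
crate_canonical <- function(crate) {
  ids <- sort(names(crate$graph), method = "radix")
  out <- lapply(ids, function(id) {
    e <- crate$graph[[id]]
    props <- e$props[sort(names(e$props), method = "radix")]
    list(id = e$id, types = e$types,
         props = lapply(props, function(vals) lapply(vals, function(v) {
           if (is_ref(v)) list(ref = v$id) else list(lit = v)
         })))
  })
  names(out) <- ids
  out
}

#' @rdname crate_canonical
#' @export
crate_equal <- function(a, b) {
  identical(crate_canonical(a), crate_canonical(b))
}
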