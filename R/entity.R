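#' Reference to another crate entity
#'
#' Property values in an RO-Crate graph are either literals (strings, numbers,
#' booleans) or references to other entities, serialized as `{"@id": ...}`
#' objects. `ref()` creates such a reference; `is_ref()` tests for one.
#'
#' @param id Entity identifier (absolute URI, relative path, or `#`-prefixed
#'   local id). Must be a non-empty string without unescaped whitespace.
#' @return An object of class `wrroc_ref`.
#' @examples
#' ref("#annotations")
#' @export
ref <- function(id) {
  check_entity_id(id)
  structure(list(id = id), class = "wrroc_ref")
}

#' @rdname ref
#' @param x Object to test.
#' @export
is_ref <- function(x) inherits(x, "wrroc_ref")

#' @export
print.wrroc_ref <- function(x, ...) {
  cat("<ref ", x$id, ">\n", sep = "")
  invisible(x)
}

check_entity_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("entity id must be a non-empty string", call. = FALSE)
  if (grepl("[[:space:]]", id))
    stop("entity id must not contain unescaped whitespace: ", dQuote(id),
         call. = FALSE)
  invisible(id)
}

#' Create a crate entity
#'
#' An entity is one node of the crate graph: an identifier, a non-empty set
#' of types, and a property map whose values are lists of literals and
#' [ref()] references. Single values and one-element lists are semantically
#' identical; properties are normalized to lists internally.
#'
#' @param id Entity identifier.
#' @param types Character vector of type terms (e.g. `"CreateAction"`,
#'   `"File"`); order is preserved.
#' @param ... Named properties. Each may be a literal, a [ref()], or a list
#'   of these.
#' @return An object of class `wrroc_entity`.
#' @examples
#' entity("#annotations", "FormalParameter", name = "annotations")
#' @export
entity <- function(id, types, ...) {
  check_entity_id(id)
  types <- as.character(types)
  if (length(types) == 0L) stop("entity ", dQuote(id), " must have at least one type",
                                call. = FALSE)
  props <- normalize_props(list(...))
  structure(list(id = id, types = unique(types), props = props),
            class = "wrroc_entity")
}

#' Normalize an entity property map
#'
#' Wraps single values into one-element lists and flattens nested lists of
#' values, so that every property is a plain list of literals and references.
#' Normalization is idempotent.
#'
#' @param props Named list of property values.
#' @return Named list with every value a list of scalar literals or [ref()]s.
#' @export
normalize_props <- function(props) {
  if (length(props) == 0L) return(structure(list(), names = character()))
  if (is.null(names(props)) || any(!nzchar(names(props))))
    stop("all properties must be named", call. = FALSE)
  lapply(props, normalize_value)
}

normalize_value <- function(v) {
  if (is_ref(v)) return(list(v))
  if (is.list(v)) {
    out <- list()
    for (el in v) out <- c(out, normalize_value(el))
    return(out)
  }
  if (is.atomic(v) && !is.null(v)) {
    if (length(v) == 0L) return(list())
    return(as.list(v))
  }
  if (is.null(v)) return(list())
  stop("unsupported property value of class ", paste(class(v), collapse = "/"),
       call. = FALSE)
}

#' Access entity properties
#'
#' `prop_values()` returns the (normalized) list of values of a property,
#' empty list if unset. `prop_ids()` returns the ids of its reference values.
#' `first_literal()` returns the first literal value or `NA`.
#'
#' @param e A [entity()].
#' @param name Property name.
#' @return See each description.
#' @export
prop_values <- function(e, name) {
  v <- e$props[[name]]
  if (is.null(v)) list() else v
}

#' @rdname prop_values
#' @export
prop_ids <- function(e, name) {
  vals <- prop_values(e, name)
  ids <- vapply(vals, function(x) if (is_ref(x)) x$id else NA_character_,
                character(1))
  ids[!is.na(ids)]
}

#' @rdname prop_values
#' @export
first_literal <- function(e, name) {
  for (v in prop_values(e, name)) if (!is_ref(v)) return(v)
  NA
}

has_type <- function(e, type) type %in% e$types

#' @export
print.wrroc_entity <- function(x, ...) {
  cat("<entity ", x$id, "> [", paste(x$types, collapse = ", "), "]\n", sep = "")
  for (nm in names(x$props)) {
    vals <- vapply(x$props[[nm]], function(v) {
      if (is_ref(v)) paste0("{", v$id, "}") else format(v)
    }, character(1))
    cat("  ", nm, ": ", paste(vals, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.wrroc_entity <- function(x, ...) {
  paste0("<entity ", x$id, ">")
}
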