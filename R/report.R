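#' Parse an ISO 8601 timestamp with offset
#'
#' Accepts `2023-05-09T05:10:53.937305+00:00` style strings (also `Z` and
#' colon-free offsets, with or without fractional seconds). Returns `NA` for
#' unparseable input; report ordering places such actions last.
#'
#' @param x Timestamp string.
#' @return A `POSIXct` (UTC) or `NA`.
#' @export
parse_time <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(as.POSIXct(NA))
  x <- as.character(x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  if (is.na(out)) out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  out
}

action_sort_order <- function(crate, actions) {
  ids <- vapply(actions, `[[`, character(1), "id")
  times <- vapply(actions, function(a) {
    as.numeric(parse_time(first_literal(a, "startTime")))
  }, numeric(1))
  times[is.na(times)] <- Inf
  order(times, ids, method = "radix")
}

value_display <- function(crate, id) {
  e <- resolve(crate, id)
  if (!is.null(e) && has_type(e, "PropertyValue")) {
    v <- first_literal(e, "value")
    if (!is.na(v)) return(as.character(v))
  }
  id
}

owned_params <- function(crate, instrument_id, direction) {
  instr <- resolve(crate, instrument_id)
  if (is.null(instr)) return(character())
  prop_ids(instr, direction)
}

pair_values <- function(crate, member_ids, owned) {
  lapply(member_ids, function(id) {
    e <- resolve(crate, id)
    params <- if (is.null(e)) character() else prop_ids(e, "exampleOfWork")
    hit <- params[params %in% owned]
    list(value = value_display(crate, id), entity = id,
         parameter = if (length(hit)) hit[[1L]] else NA_character_)
  })
}

step_of_action <- function(crate, action_id) {
  for (ca in entities_of_type(crate, "ControlAction")) {
    if (action_id %in% prop_ids(ca, "object")) {
      instr <- prop_ids(ca, "instrument")
      if (length(instr)) return(instr[[1L]])
    }
  }
  NA_character_
}

#' Summarize the executions recorded in a crate
#'
#' One summary per `CreateAction`, ordered by parsed start time ascending
#' (ties and missing times fall back to id order, actions without a start
#' time last). Each summary pairs the action's actual input and output
#' values with the formal parameters they realized: a value pairs with a
#' parameter when its `exampleOfWork` points at a parameter owned (via
#' `input`/`output`) by the action's instrument. Values realizing only
#' parameters of other tools keep an empty parameter slot rather than a
#' guessed one. Partial crates yield partial summaries; the report is a pure
#' function of the document.
#'
#' @param crate A crate.
#' @return A list of `wrroc_action_summary` objects, classed
#'   `wrroc_report`.
#' @export
action_report <- function(crate) {
  actions <- unname(entities_of_type(crate, "CreateAction"))
  actions <- actions[action_sort_order(crate, actions)]
  out <- lapply(actions, function(a) {
    instr_id <- prop_ids(a, "instrument")
    instr_id <- if (length(instr_id)) instr_id[[1L]] else NA_character_
    instr <- if (!is.na(instr_id)) resolve(crate, instr_id) else NULL
    structure(list(
      action = a$id,
      step = step_of_action(crate, a$id),
      instrument = instr_id,
      instrument_types = if (is.null(instr)) character() else instr$types,
      started = as.character(first_literal(a, "startTime")),
      ended = as.character(first_literal(a, "endTime")),
      inputs = pair_values(crate, prop_ids(a, "object"),
                           owned_params(crate, instr_id, "input")),
      outputs = pair_values(crate, prop_ids(a, "result"),
                            owned_params(crate, instr_id, "output"))
    ), class = "wrroc_action_summary")
  })
  structure(out, class = "wrroc_report")
}

#' Render a report as text
#'
#' Plain-text layout: per action an `action:` line, then optional `step:`,
#' `instrument: <id> (['type', ...])`, `started:`/`ended:` when recorded,
#' and `inputs:`/`outputs:` sections with one `<value> <- <parameter>` line
#' per bound value (values without an owned parameter print alone).
#'
#' @param report An [action_report()] result.
#' @return Character scalar (lines joined with newlines).
#' @export
render_report <- function(report) {
  lines <- character()
  for (s in report) {
    lines <- c(lines, paste0("action: ", s$action))
    if (!is.na(s$step)) lines <- c(lines, paste0(" step: ", s$step))
    if (!is.na(s$instrument)) {
      tl <- paste0("['", paste(s$instrument_types, collapse = "', '"), "']")
      lines <- c(lines, paste0(" instrument: ", s$instrument, " (", tl, ")"))
    }
    if (!is.na(s$started)) lines <- c(lines, paste0(" started: ", s$started))
    if (!is.na(s$ended)) lines <- c(lines, paste0(" ended: ", s$ended))
    for (dir in c("inputs", "outputs")) {
      vals <- s[[dir]]
      if (length(vals) == 0L) next
      lines <- c(lines, paste0(" ", dir, ":"))
      for (v in vals) {
        lines <- c(lines, if (is.na(v$parameter)) paste0("  ", v$value)
                   else paste0("  ", v$value, " <- ", v$parameter))
      }
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.wrroc_report <- function(x, ...) {
  cat(render_report(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.wrroc_report <- function(x, ...) render_report(x)

#' Tabulate all actions with instrument and times
#'
#' The fixed traversal equivalent of the standard "all actions" RDF query:
#' one row per `CreateAction` with its instrument and optional start/end
#' times (`NA` when unset).
#'
#' @param crate A crate.
#' @return Data frame with columns `action`, `instrument`, `start`, `end`.
#' @export
query_actions <- function(crate) {
  actions <- unname(entities_of_type(crate, "CreateAction"))
  actions <- actions[action_sort_order(crate, actions)]
  data.frame(
    action = vapply(actions, `[[`, character(1), "id"),
    instrument = vapply(actions, function(a) {
      i <- prop_ids(a, "instrument"); if (length(i)) i[[1L]] else NA_character_
    }, character(1)),
    start = vapply(actions, function(a)
      as.character(first_literal(a, "startTime")), character(1)),
    end = vapply(actions, function(a)
      as.character(first_literal(a, "endTime")), character(1)),
    stringsAsFactors = FALSE)
}

connection_edges <- function(crate) {
  pcs <- entities_of_type(crate, "ParameterConnection")
  holder_of <- list()
  for (h in crate$graph)
    for (cid in prop_ids(h, "connection")) holder_of[[cid]] <- h$id
  do.call(rbind, c(list(data.frame(source = character(), target = character(),
                                   holder = character(),
                                   stringsAsFactors = FALSE)),
                   lapply(pcs, function(pc) {
    s <- prop_ids(pc, "sourceParameter"); t <- prop_ids(pc, "targetParameter")
    if (length(s) == 0L || length(t) == 0L) return(NULL)
    data.frame(source = s[[1L]], target = t[[1L]],
               holder = holder_of[[pc$id]] %||% NA_character_,
               stringsAsFactors = FALSE)
  })))
}

param_owner <- function(crate, param_id) {
  for (e in crate$graph)
    if (param_id %in% c(prop_ids(e, "input"), prop_ids(e, "output")))
      return(e$id)
  NA_character_
}

#' Which tool parameters does a workflow parameter reach?
#'
#' Follows the transitive closure of parameter connections starting at the
#' given parameter, reporting every hop as (holding step, owning tool,
#' target parameter) in traversal order. This answers "which tool is
#' affected by this workflow-level parameter".
#'
#' @param crate A crate.
#' @param workflow_param Id of a `FormalParameter`.
#' @return Data frame with columns `step`, `tool`, `parameter`.
#' @export
affected_by <- function(crate, workflow_param) {
  p <- resolve(crate, workflow_param)
  if (is.null(p) || !has_type(p, "FormalParameter"))
    stop("unknown parameter: ", dQuote(workflow_param), call. = FALSE)
  edges <- connection_edges(crate)
  seen <- character()
  frontier <- workflow_param
  rows <- data.frame(step = character(), tool = character(),
                     parameter = character(), stringsAsFactors = FALSE)
  while (length(frontier)) {
    nxt <- character()
    for (src in frontier) {
      hits <- edges[edges$source == src, , drop = FALSE]
      for (i in seq_len(nrow(hits))) {
        tgt <- hits$target[i]
        if (tgt %in% seen) next
        seen <- c(seen, tgt)
        rows <- rbind(rows, data.frame(step = hits$holder[i],
                                       tool = param_owner(crate, tgt),
                                       parameter = tgt,
                                       stringsAsFactors = FALSE))
        nxt <- c(nxt, tgt)
      }
    }
    frontier <- nxt
  }
  rows
}

#' Data entities downstream of an entity
#'
#' Follows the implicit-workflow dependency relation: an entity feeds every
#' action that lists it in `object`, and each such action feeds its `result`
#' entities. Returns everything reachable from `entity_id` (excluding
#' itself) in breadth-first order. Adding an action never removes
#' reachability.
#'
#' @param crate A crate.
#' @param entity_id Id of a data entity in the crate.
#' @return Character vector of entity ids.
#' @export
downstream_data <- function(crate, entity_id) {
  require_entity(crate, entity_id)
  actions <- entities_of_type(crate, "CreateAction")
  reached <- character()
  frontier <- entity_id
  while (length(frontier)) {
    nxt <- character()
    for (a in actions) {
      if (any(frontier %in% prop_ids(a, "object"))) {
        for (r in prop_ids(a, "result")) {
          if (r != entity_id && !r %in% reached) {
            reached <- c(reached, r)
            nxt <- c(nxt, r)
          }
        }
      }
    }
    frontier <- nxt
  }
  reached
}
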