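#' Serialize a trial specification to canonical JSON
#'
#' Trials are exchanged as a single JSON document with the four component
#' categories (`goal`, `interventions`, `measures`, `schedule`) plus `id`,
#' `design` and `created_at` at the top level. Serialization is canonical:
#' UTF-8, object keys sorted alphabetically at every level, optional fields
#' omitted when absent, arrays kept as arrays even when length one.
#'
#' @param spec A valid `nof1_trial`.
#' @param pretty Indent the output for human readers.
#' @return A length-one character vector of JSON text.
#' @seealso [trial_from_json()]
#' @export
trial_to_json <- function(spec, pretty = FALSE) {
  stop_if_invalid(spec)
  payload <- sort_keys(spec_to_payload(spec))
  as.character(jsonlite::toJSON(
    payload,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = pretty
  ))
}

#' Parse a trial specification from JSON
#'
#' The inverse of [trial_to_json()]: `trial_from_json(trial_to_json(s))` is
#' identical to `s` for every valid spec. Two failure modes are distinguished
#' by condition class: malformed JSON raises a *parse* error
#' (`nof1_error_parse`), while well-formed JSON that is not a valid trial
#' raises a *schema* error (`nof1_error_schema`) naming the offending paths.
#'
#' @param text JSON text (or a connection/file path accepted by
#'   [jsonlite::fromJSON()] when it is a single string naming a file).
#' @param partial If `TRUE`, missing or invalid fields are tolerated and the
#'   partially filled spec is returned for [validate_trial()] to report on,
#'   mirroring an in-progress creation flow.
#' @return A `nof1_trial`.
#' @export
trial_from_json <- function(text, partial = FALSE) {
  parsed <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      abort_nof1("parse", paste0("malformed JSON: ", conditionMessage(e)))
    }
  )
  if (!is.list(parsed)) {
    abort_nof1("schema", "trial JSON must be an object")
  }

  if (!partial) {
    required <- c("id", "created_at", "goal", "design", "interventions",
                  "measures", "schedule")
    missing <- setdiff(required, names(parsed))
    if (length(missing) > 0) {
      abort_nof1("schema", paste0(
        "trial JSON is missing required field(s): ",
        paste(missing, collapse = ", ")
      ), paths = missing)
    }
  }

  spec <- structure(
    compact_list(list(
      id = as_string_or_null(parsed$id),
      created_at = as_string_or_null(parsed$created_at),
      goal = if (!is.null(parsed$goal)) rebuild_goal(parsed$goal),
      design = as_string_or_null(parsed$design),
      interventions = lapply(parsed$interventions %||% list(), rebuild_intervention),
      measures = lapply(parsed$measures %||% list(), rebuild_measure),
      schedule = if (!is.null(parsed$schedule)) rebuild_schedule(parsed$schedule)
    )),
    class = "nof1_trial"
  )

  if (!partial) {
    report <- validate_trial(spec)
    if (nrow(report) > 0) {
      abort_nof1("schema", paste0(
        "JSON parsed but is not a valid trial spec: ",
        paste(unique(report$path), collapse = ", ")
      ), report = report, paths = report$path)
    }
  }
  spec
}

# --- payload construction (R -> JSON-ready lists) --------------------------

spec_to_payload <- function(spec) {
  list(
    id = spec$id,
    created_at = spec$created_at,
    goal = compact_list(list(
      name = spec$goal$name,
      rationale = spec$goal$rationale
    )),
    design = spec$design,
    interventions = lapply(spec$interventions, function(i) {
      list(
        id = i$id, name = i$name, instructions = i$instructions,
        reminder = reminder_payload(i$reminder)
      )
    }),
    measures = lapply(spec$measures, measure_payload),
    schedule = list(
      phase_duration_days = spec$schedule$phase_duration_days,
      n_phase_pairs = spec$schedule$n_phase_pairs,
      order = spec$schedule$order
    )
  )
}

reminder_payload <- function(r) {
  compact_list(list(
    times = as.list(r$times),  # force a JSON array even for one time
    recurrence = r$recurrence,
    interval_days = r$interval_days
  ))
}

measure_payload <- function(m) {
  out <- list(id = m$id, name = m$name, input_type = m$input_type)
  if (m$input_type == "keyboard") {
    out$keyboard_config <- list(unit = m$keyboard_config$unit)
  } else if (m$input_type == "list") {
    out$list_config <- list(items = as.list(m$list_config$items))
  } else if (m$input_type == "scale") {
    out$scale_config <- list(
      min = m$scale_config$min,
      max = m$scale_config$max,
      annotations = lapply(m$scale_config$annotations, function(a) {
        list(position = a$position, label = a$label)
      })
    )
  }
  out$reminder <- reminder_payload(m$reminder)
  out
}

sort_keys <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, sort_keys)
  if (!is.null(names(x)) && all(nzchar(names(x)))) x[order(names(x))] else x
}

# --- rebuilders (JSON lists -> internal representation) --------------------

as_string_or_null <- function(x) if (is.null(x)) NULL else as.character(x)

chr_vec <- function(x) as.character(unlist(x, use.names = FALSE))

rebuild_goal <- function(g) {
  compact_list(list(
    name = as_string_or_null(g$name),
    rationale = as_string_or_null(g$rationale)
  ))
}

rebuild_reminder <- function(r) {
  if (is.null(r)) return(NULL)
  out <- list(
    times = if (!is.null(r$times)) chr_vec(r$times) else character(),
    recurrence = as_string_or_null(r$recurrence) %||% NA_character_
  )
  if (!is.null(r$interval_days)) out$interval_days <- as.integer(r$interval_days)
  out
}

rebuild_intervention <- function(i) {
  compact_list(list(
    id = as_string_or_null(i$id),
    name = as_string_or_null(i$name),
    instructions = as_string_or_null(i$instructions) %||% "",
    reminder = rebuild_reminder(i$reminder)
  ))
}

rebuild_measure <- function(m) {
  out <- list(
    id = as_string_or_null(m$id),
    name = as_string_or_null(m$name),
    input_type = as_string_or_null(m$input_type)
  )
  if (!is.null(m$keyboard_config)) {
    out$keyboard_config <- list(unit = as_string_or_null(m$keyboard_config$unit) %||% "")
  }
  if (!is.null(m$list_config)) {
    out$list_config <- list(items = chr_vec(m$list_config$items))
  }
  if (!is.null(m$scale_config)) {
    sc <- m$scale_config
    out$scale_config <- list(
      min = as.numeric(sc$min %||% NA_real_),
      max = as.numeric(sc$max %||% NA_real_),
      annotations = lapply(sc$annotations %||% list(), function(a) {
        list(position = as.numeric(a$position), label = as.character(a$label))
      })
    )
  }
  out$reminder <- rebuild_reminder(m$reminder)
  compact_list(out)
}

rebuild_schedule <- function(s) {
  compact_list(list(
    phase_duration_days = if (!is.null(s$phase_duration_days)) as.integer(s$phase_duration_days),
    n_phase_pairs = if (!is.null(s$n_phase_pairs)) as.integer(s$n_phase_pairs),
    order = as_string_or_null(s$order)
  ))
}
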