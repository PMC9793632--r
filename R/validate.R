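#' Validate a trial specification
#'
#' Checks a (possibly partially filled) trial specification against every
#' structural invariant and returns the violations as data rather than
#' raising errors, mirroring a step-by-step creation flow where completeness
#' is reported back to the user section by section.
#'
#' Checked invariants include: all four components present; non-empty
#' component names; the design/intervention-count coupling (withdrawal needs
#' exactly 1 intervention, alternating treatment exactly 2); measure configs
#' matching their input type (scale `min < max`, annotations within range,
#' lists with at least 2 distinct items); reminder times valid and strictly
#' increasing with `interval_days >= 2` present exactly when recurrence is
#' `every_x_days`; and schedule integers `d >= 1`, `p >= 1` with a known
#' order.
#'
#' @param spec A `nof1_trial` or any named list shaped like one.
#' @return A tibble with one row per violation and columns `code`
#'   (machine-readable violation code), `path` (offending field, e.g.
#'   `"measures[2]/scale_config"`) and `message`. Zero rows means the spec is
#'   valid.
#' @examples
#' bad <- nof1_trial(
#'   goal = goal("Less back pain"),
#'   interventions = list(intervention("Warming pad"), intervention("Arnica gel")),
#'   measures = list(measure_scale("Pain", min = 10, max = 1)),
#'   design = "withdrawal"
#' )
#' validate_trial(bad)
#' @export
validate_trial <- function(spec) {
  v <- violation_collector()

  if (!is.list(spec)) {
    v$add("not_a_spec", "", "trial spec must be a named list")
    return(v$report())
  }

  # -- identity -----------------------------------------------------------
  if (!is_nonempty_string(spec$id)) {
    v$add("missing_id", "id", "trial id must be a non-empty string")
  }
  if (is.null(spec$created_at)) {
    v$add("missing_created_at", "created_at", "created_at timestamp is required")
  }

  # -- goal ---------------------------------------------------------------
  if (is.null(spec$goal)) {
    v$add("missing_component", "goal", "trial has no goal")
  } else if (!is_nonempty_string(spec$goal$name)) {
    v$add("empty_name", "goal/name", "goal name must be a non-empty string")
  }

  # -- design + interventions --------------------------------------------
  n_int <- length(spec$interventions)
  if (is.null(spec$design)) {
    v$add("missing_component", "design", "trial design is not set")
  } else if (!spec$design %in% c("withdrawal", "alternating_treatment")) {
    v$add("design_unknown", "design",
          paste0("unknown design '", spec$design, "'"))
  } else {
    expected <- if (spec$design == "withdrawal") 1L else 2L
    if (n_int != expected) {
      v$add("design_interventions_mismatch", "design/interventions", paste0(
        "design '", spec$design, "' requires exactly ", expected,
        " intervention(s), found ", n_int
      ))
    }
  }
  if (n_int == 0) {
    v$add("missing_component", "interventions", "trial has no interventions")
  }
  for (k in seq_along(spec$interventions)) {
    validate_intervention(spec$interventions[[k]], sprintf("interventions[%d]", k), v)
  }

  # -- measures -----------------------------------------------------------
  if (length(spec$measures) == 0) {
    v$add("missing_component", "measures", "trial must define at least one measure")
  }
  for (k in seq_along(spec$measures)) {
    validate_measure(spec$measures[[k]], sprintf("measures[%d]", k), v)
  }

  # -- schedule -----------------------------------------------------------
  if (is.null(spec$schedule)) {
    v$add("missing_component", "schedule", "trial has no schedule")
  } else {
    validate_schedule(spec$schedule, "schedule", v)
  }

  v$report()
}

violation_collector <- function() {
  rows <- list()
  list(
    add = function(code, path, message) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        code = code, path = path, message = message
      )
    },
    report = function() {
      if (length(rows) == 0) {
        tibble::tibble(code = character(), path = character(), message = character())
      } else {
        dplyr::bind_rows(rows)
      }
    }
  )
}

validate_intervention <- function(x, path, v) {
  if (!is_nonempty_string(x$name)) {
    v$add("empty_name", paste0(path, "/name"), "intervention name must be non-empty")
  }
  if (!is_nonempty_string(x$id)) {
    v$add("missing_id", paste0(path, "/id"), "intervention id must be non-empty")
  }
  if (is.null(x$reminder)) {
    v$add("reminder_missing", paste0(path, "/reminder"),
          "every intervention needs a reminder policy")
  } else {
    validate_reminder(x$reminder, paste0(path, "/reminder"), v)
  }
}

validate_measure <- function(x, path, v) {
  if (!is_nonempty_string(x$name)) {
    v$add("empty_name", paste0(path, "/name"), "measure name must be non-empty")
  }
  if (!is_nonempty_string(x$id)) {
    v$add("missing_id", paste0(path, "/id"), "measure id must be non-empty")
  }

  types <- c("keyboard", "list", "scale")
  configs <- c(keyboard = "keyboard_config", list = "list_config", scale = "scale_config")
  if (is.null(x$input_type) || !x$input_type %in% types) {
    v$add("input_type_unknown", paste0(path, "/input_type"), paste0(
      "input_type must be one of ", paste(types, collapse = ", ")
    ))
  } else {
    needed <- configs[[x$input_type]]
    present <- intersect(names(x), unname(configs))
    if (!needed %in% present || length(setdiff(present, needed)) > 0) {
      v$add("config_mismatch", paste0(path, "/", needed), paste0(
        "measure with input_type '", x$input_type, "' must carry exactly ", needed
      ))
    }
    if (x$input_type == "scale" && !is.null(x$scale_config)) {
      sc <- x$scale_config
      ok_bounds <- is.numeric(sc$min) && is.numeric(sc$max) &&
        length(sc$min) == 1 && length(sc$max) == 1 && sc$min < sc$max
      if (!ok_bounds) {
        v$add("scale_range", paste0(path, "/scale_config"),
              "scale requires numeric bounds with min < max")
      } else {
        for (a in sc$annotations %||% list()) {
          if (!is.numeric(a$position) || a$position < sc$min || a$position > sc$max) {
            v$add("scale_annotation_out_of_range",
                  paste0(path, "/scale_config/annotations"), paste0(
                    "annotation position ", a$position %||% "?",
                    " outside [", sc$min, ", ", sc$max, "]"
                  ))
          }
        }
      }
    }
    if (x$input_type == "list" && !is.null(x$list_config)) {
      items <- x$list_config$items
      if (!is.character(items) || length(unique(items)) < 2 || any(!nzchar(items))) {
        v$add("list_items", paste0(path, "/list_config/items"),
              "list measures need at least 2 distinct non-empty items")
      }
    }
  }

  if (is.null(x$reminder)) {
    v$add("reminder_missing", paste0(path, "/reminder"),
          "every measure needs a reminder policy")
  } else {
    validate_reminder(x$reminder, paste0(path, "/reminder"), v)
  }
}

validate_reminder <- function(r, path, v) {
  times <- r$times
  if (!is.character(times) || length(times) == 0 || !all(is_hhmm(times))) {
    v$add("reminder_times", paste0(path, "/times"),
          "reminder times must be one or more HH:MM strings")
  } else if (length(times) > 1) {
    mins <- hhmm_to_minutes(times)
    if (any(diff(mins) <= 0)) {
      v$add("reminder_times", paste0(path, "/times"),
            "reminder times must be strictly increasing within the day")
    }
  }
  if (is.null(r$recurrence) || !r$recurrence %in% c("daily", "every_x_days")) {
    v$add("reminder_recurrence", paste0(path, "/recurrence"),
          "recurrence must be 'daily' or 'every_x_days'")
  } else if (r$recurrence == "every_x_days") {
    if (!is_count(r$interval_days, min = 2L)) {
      v$add("reminder_interval", paste0(path, "/interval_days"),
            "every_x_days requires an integer interval_days >= 2")
    }
  } else if (!is.null(r$interval_days)) {
    v$add("reminder_interval", paste0(path, "/interval_days"),
          "interval_days is only allowed with recurrence 'every_x_days'")
  }
}

validate_schedule <- function(s, path, v) {
  if (!is_count(s$phase_duration_days, min = 1L)) {
    v$add("schedule_phase_duration", paste0(path, "/phase_duration_days"),
          "phase duration must be an integer >= 1 day")
  }
  if (!is_count(s$n_phase_pairs, min = 1L)) {
    v$add("schedule_phase_pairs", paste0(path, "/n_phase_pairs"),
          "number of phase pairs must be an integer >= 1")
  }
  if (is.null(s$order) || !s$order %in% c("alternating", "counterbalanced")) {
    v$add("schedule_order", paste0(path, "/order"),
          "order must be 'alternating' or 'counterbalanced'")
  }
}

stop_if_invalid <- function(spec) {
  report <- validate_trial(spec)
  if (nrow(report) > 0) {
    abort_nof1("invalid_spec", paste0(
      "invalid trial spec (", nrow(report), " violation(s)): ",
      paste(utils::head(report$code, 3), collapse = ", "),
      if (nrow(report) > 3) ", ..." else ""
    ))
  }
  invisible(spec)
}
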