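#' Build an N-of-1 trial specification
#'
#' An N-of-1 trial is a multi-period crossover experiment run in a single
#' person. A trial specification has four components: a *goal* (what the
#' person wants to achieve), one or two *interventions* (what they try out),
#' one or more *measures* (the data they record to judge goal attainment),
#' and a *schedule* (phase length, number of phase pairs, and phase order).
#'
#' Two designs are supported. A *withdrawal* design evaluates a single
#' intervention by alternating intervention (A) and no-intervention (B)
#' phases. An *alternating-treatment* design compares two interventions, the
#' first applied in A phases and the second in B phases. The design is
#' therefore coupled to the number of interventions: exactly one for
#' withdrawal, exactly two for alternating treatment.
#'
#' @param goal A [goal()] object.
#' @param interventions A list of [intervention()] objects (length 1 or 2).
#' @param measures A non-empty list of measure objects, see [measure_keyboard()],
#'   [measure_list()], [measure_scale()].
#' @param design `"withdrawal"` or `"alternating_treatment"`. Defaults to the
#'   design implied by the number of interventions.
#' @param schedule A [schedule()] object; defaults to [default_schedule()].
#' @param id Opaque trial identifier; a fresh UUID-format string by default.
#' @param created_at Creation timestamp (`"YYYY-MM-DDTHH:MM:SS"`, local,
#'   timezone-naive); defaults to the current time.
#'
#' @return A `nof1_trial` object (a named list with the four components plus
#'   `id`, `design` and `created_at`).
#' @seealso [validate_trial()], [trial_to_json()], [phase_calendar()]
#' @examples
#' trial <- nof1_trial(
#'   goal = goal("Improve sleep"),
#'   interventions = list(intervention("Meditation", "10 minutes before bed")),
#'   measures = list(measure_scale("Sleep quality", min = 0, max = 10))
#' )
#' validate_trial(trial)
#' @export
nof1_trial <- function(goal, interventions, measures,
                       design = NULL,
                       schedule = default_schedule(),
                       id = new_id(),
                       created_at = now_timestamp()) {
  if (!is.list(interventions) || (length(interventions) > 0 && !is.list(interventions[[1]]))) {
    interventions <- list(interventions)
  }
  if (!is.list(measures) || (length(measures) > 0 && !is.list(measures[[1]]))) {
    measures <- list(measures)
  }
  if (is.null(design)) {
    design <- if (length(interventions) >= 2) "alternating_treatment" else "withdrawal"
  }
  spec <- structure(
    list(
      id = as.character(id),
      created_at = as.character(created_at),
      goal = goal,
      design = design,
      interventions = unname(interventions),
      measures = unname(measures),
      schedule = schedule
    ),
    class = "nof1_trial"
  )
  spec
}

#' Trial components
#'
#' Constructors for the building blocks of a trial specification: the goal,
#' interventions, measures (one of three input types) and reminder policies.
#'
#' Measures come in three input types, mirroring how a value is entered:
#' * `keyboard` — a free numeric value with a unit label (e.g. hours slept);
#' * `list` — a choice from at least two configured items (e.g. yes/no);
#' * `scale` — a number on a bounded scale `[min, max]`, optionally annotated
#'   at positions within the range (annotations are display metadata only).
#'
#' A reminder policy holds one or more times of day (`"HH:MM"`) and a
#' recurrence: `daily`, or `every_x_days` with an interval of at least 2 days
#' anchored at trial day 1.
#'
#' @param name Short non-empty component name.
#' @param rationale Optional free-text motivation for the goal.
#' @param instructions Free-text instructions for carrying out the intervention.
#' @param reminder A [reminder_policy()].
#' @param unit Unit label for keyboard measures (a label, not a dimensioned
#'   quantity; no conversion is performed).
#' @param items Character vector of at least two distinct list items.
#' @param min,max Scale bounds, `min < max`; scale values are real numbers in
#'   `[min, max]`.
#' @param annotations Optional list of `list(position =, label =)` entries;
#'   every position must lie in `[min, max]`.
#' @param times Character vector of `"HH:MM"` times, strictly increasing.
#' @param recurrence `"daily"` or `"every_x_days"`.
#' @param interval_days Integer interval `x >= 2`; required (and only allowed)
#'   when `recurrence = "every_x_days"`.
#' @param id Component identifier, auto-generated when omitted.
#'
#' @return A named list representing the component.
#' @name trial-components
NULL

#' @rdname trial-components
#' @export
goal <- function(name, rationale = NULL) {
  compact_list(list(name = as.character(name), rationale = rationale))
}

#' @rdname trial-components
#' @export
intervention <- function(name, instructions = "", reminder = reminder_policy(), id = new_id()) {
  list(
    id = as.character(id),
    name = as.character(name),
    instructions = as.character(instructions),
    reminder = reminder
  )
}

#' @rdname trial-components
#' @export
reminder_policy <- function(times = "08:00", recurrence = "daily", interval_days = NULL) {
  out <- list(times = as.character(times), recurrence = as.character(recurrence))
  if (!is.null(interval_days)) out$interval_days <- as.integer(interval_days)
  out
}

#' @rdname trial-components
#' @export
measure_keyboard <- function(name, unit = "", reminder = reminder_policy(), id = new_id()) {
  list(
    id = as.character(id),
    name = as.character(name),
    input_type = "keyboard",
    keyboard_config = list(unit = as.character(unit)),
    reminder = reminder
  )
}

#' @rdname trial-components
#' @export
measure_list <- function(name, items, reminder = reminder_policy(), id = new_id()) {
  list(
    id = as.character(id),
    name = as.character(name),
    input_type = "list",
    list_config = list(items = as.character(items)),
    reminder = reminder
  )
}

#' @rdname trial-components
#' @export
measure_scale <- function(name, min, max, annotations = list(),
                          reminder = reminder_policy(), id = new_id()) {
  annotations <- lapply(annotations, function(a) {
    list(position = as.numeric(a$position), label = as.character(a$label))
  })
  list(
    id = as.character(id),
    name = as.character(name),
    input_type = "scale",
    scale_config = list(min = as.numeric(min), max = as.numeric(max), annotations = annotations),
    reminder = reminder
  )
}

#' Trial schedule
#'
#' A schedule is a phase duration `d` (days per phase), a number of phase
#' pairs `p`, and an ordering rule. Phases always come in AB or BA pairs so
#' the sequence stays balanced (equal numbers of A and B phases), which keeps
#' the design analysable when temporal effects are present. `alternating`
#' repeats AB (giving ABAB...), `counterbalanced` alternates the pair
#' orientation (AB, BA, AB, ... giving ABBA...).
#'
#' @param phase_duration_days Days per phase, integer `d >= 1`.
#' @param n_phase_pairs Number of AB/BA pairs, integer `p >= 1`.
#' @param order `"alternating"` or `"counterbalanced"`.
#' @return A named list with the three fields.
#' @seealso [default_schedule()], [generate_phase_sequence()], [total_duration()]
#' @export
schedule <- function(phase_duration_days, n_phase_pairs, order = "alternating") {
  list(
    phase_duration_days = as.integer(phase_duration_days),
    n_phase_pairs = as.integer(n_phase_pairs),
    order = as.character(order)
  )
}

#' Default trial schedule
#'
#' The default schedule is two phase pairs of seven days each in alternating
#' order, i.e. the phase sequence ABAB with a total duration of 28 days.
#'
#' @return A [schedule()] with `d = 7`, `p = 2`, `order = "alternating"`.
#' @export
default_schedule <- function() schedule(7L, 2L, "alternating")

#' Clone a trial specification
#'
#' Deep-copies a valid trial so it can be edited independently, assigning a
#' fresh id and creation timestamp. Component ids are kept so logs recorded
#' against the original remain interpretable against the clone.
#'
#' @param spec A valid `nof1_trial`.
#' @param id,created_at Overrides for the fresh identity.
#' @return A new `nof1_trial`.
#' @export
clone_trial <- function(spec, id = new_id(), created_at = now_timestamp()) {
  report <- validate_trial(spec)
  if (nrow(report) > 0) {
    abort_nof1("invalid_spec", paste0(
      "cannot clone an invalid trial spec (", nrow(report), " violation(s); ",
      "see validate_trial())"
    ))
  }
  out <- spec
  out$id <- as.character(id)
  out$created_at <- as.character(created_at)
  out
}

#' @export
print.nof1_trial <- function(x, ...) {
  cat("<nof1_trial> ", x$goal$name %||% "(no goal)", "\n", sep = "")
  cat("  design:        ", x$design %||% "(unset)", "\n", sep = "")
  cat("  interventions: ",
      paste(vapply(x$interventions, function(i) i$name %||% "?", character(1)),
            collapse = ", "), "\n", sep = "")
  cat("  measures:      ",
      paste(vapply(x$measures, function(m) {
        paste0(m$name %||% "?", " [", m$input_type %||% "?", "]")
      }, character(1)), collapse = ", "), "\n", sep = "")
  s <- x$schedule
  if (!is.null(s)) {
    cat("  schedule:      ", s$n_phase_pairs, " pair(s) x ", s$phase_duration_days,
        " day(s), ", s$order, " (", total_duration(s), " days total)\n", sep = "")
  }
  invisible(x)
}

find_measure <- function(spec, measure_id) {
  for (m in spec$measures) {
    if (identical(m$id, measure_id)) return(m)
  }
  abort_nof1("unknown_measure", paste0("no measure with id '", measure_id, "' in trial"))
}

find_intervention <- function(spec, intervention_id) {
  for (i in spec$interventions) {
    if (identical(i$id, intervention_id)) return(i)
  }
  abort_nof1("unknown_intervention", paste0("no intervention with id '", intervention_id, "'"))
}
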