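#' Aggregate a numeric measure by day or by phase
#'
#' Computes the arithmetic mean of a keyboard or scale measure's observations
#' at the chosen grain. Day grain groups by trial day; phase grain groups by
#' phase ordinal and *pools raw observations* within the phase (the phase
#' mean is the mean over all its observations, not the mean of daily means,
#' so days with more entries weigh proportionally more). Days or phases with
#' no data are omitted, never imputed.
#'
#' @param log An observation tibble.
#' @param spec A valid `nof1_trial`.
#' @param measure_id Id of a keyboard or scale measure.
#' @param grain `"day"` or `"phase"`.
#' @return A tibble of class `nof1_series` with columns `index` (day number
#'   or phase ordinal), `phase_label`, `n` and `mean`, ordered by `index`;
#'   attributes `measure_id` and `grain` record the request.
#' @seealso [list_frequencies()] for categorical measures, [phase_contrast()]
#' @export
aggregate_observations <- function(log, spec, measure_id, grain = c("day", "phase")) {
  grain <- match.arg(grain)
  measure <- numeric_measure(spec, measure_id)
  obs <- log[log$measure_id == measure_id, , drop = FALSE]

  if (nrow(obs) == 0) {
    out <- tibble::tibble(index = integer(), phase_label = character(),
                          n = integer(), mean = numeric())
  } else {
    obs$.value <- observation_values(obs)
    obs$index <- if (grain == "day") {
      obs$day_index
    } else {
      phase_ordinal_of_day(spec$schedule, obs$day_index)
    }
    out <- obs |>
      dplyr::group_by(.data$index, .data$phase_label) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$.value), .groups = "drop") |>
      dplyr::arrange(.data$index)
  }
  structure(out, class = c("nof1_series", class(out)),
            measure_id = measure_id, grain = grain)
}

numeric_measure <- function(spec, measure_id) {
  stop_if_invalid(spec)
  measure <- find_measure(spec, measure_id)
  if (!measure$input_type %in% c("keyboard", "scale")) {
    abort_nof1("unsupported_grain", paste0(
      "measure '", measure_id, "' is categorical (list); means are undefined — ",
      "use list_frequencies()"
    ))
  }
  measure
}

#' Per-item counts of a list measure by day or phase
#'
#' The categorical counterpart of [aggregate_observations()]: counts each
#' configured item's occurrences per day or per phase. Counts within a grain
#' unit sum to the number of observations in it; empty units are omitted.
#'
#' @inheritParams aggregate_observations
#' @param measure_id Id of a list measure.
#' @return A tibble with columns `index`, `phase_label`, `item`, `n`.
#' @export
list_frequencies <- function(log, spec, measure_id, grain = c("day", "phase")) {
  grain <- match.arg(grain)
  stop_if_invalid(spec)
  measure <- find_measure(spec, measure_id)
  if (measure$input_type != "list") {
    abort_nof1("unsupported_grain", paste0(
      "measure '", measure_id, "' is numeric; use aggregate_observations()"
    ))
  }
  obs <- log[log$measure_id == measure_id, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(tibble::tibble(index = integer(), phase_label = character(),
                          item = character(), n = integer()))
  }
  obs$index <- if (grain == "day") {
    obs$day_index
  } else {
    phase_ordinal_of_day(spec$schedule, obs$day_index)
  }
  obs |>
    dplyr::count(.data$index, .data$phase_label, item = .data$value) |>
    dplyr::arrange(.data$index, .data$item)
}

#' Phase contrast for a numeric measure
#'
#' Compares the two phase types by pooling all A-phase observations and all
#' B-phase observations. The contrast is `mean_A - mean_B`: under a
#' withdrawal design, intervention minus no-intervention; under an
#' alternating-treatment design, first minus second intervention. With
#' `with_test = TRUE` a Welch (unequal-variance) two-sample t-test is added;
#' no multiple-testing correction is applied since a single contrast is
#' computed per measure.
#'
#' @inheritParams aggregate_observations
#' @param with_test Also compute the Welch t-test (requires at least 2
#'   observations per phase type; without it, 1 suffices).
#' @return A `nof1_contrast` object with fields `measure_id`, `mean_A`,
#'   `mean_B`, `difference`, `n_A`, `n_B` and, when tested, `statistic`,
#'   `df`, `p_value`. See [tidy.nof1_contrast()].
#' @export
phase_contrast <- function(log, spec, measure_id, with_test = FALSE) {
  numeric_measure(spec, measure_id)
  obs <- log[log$measure_id == measure_id, , drop = FALSE]
  a <- observation_values(obs[obs$phase_label == "A", , drop = FALSE])
  b <- observation_values(obs[obs$phase_label == "B", , drop = FALSE])

  need <- if (with_test) 2L else 1L
  if (length(a) < need || length(b) < need) {
    abort_nof1("insufficient_data", paste0(
      "phase contrast needs at least ", need, " observation(s) per phase type; ",
      "found ", length(a), " in A and ", length(b), " in B"
    ))
  }

  out <- list(
    measure_id = measure_id,
    mean_A = mean(a), mean_B = mean(b),
    difference = mean(a) - mean(b),
    n_A = length(a), n_B = length(b)
  )
  if (with_test) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    out$statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
  }
  structure(out, class = "nof1_contrast")
}

#' @export
print.nof1_contrast <- function(x, ...) {
  cat("<nof1_contrast> measure ", x$measure_id, "\n", sep = "")
  cat(sprintf("  mean A: %.4g (n = %d)   mean B: %.4g (n = %d)\n",
              x$mean_A, x$n_A, x$mean_B, x$n_B))
  cat(sprintf("  difference (A - B): %.4g\n", x$difference))
  if (!is.null(x$statistic)) {
    cat(sprintf("  Welch t = %.4g, df = %.2f, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Descriptive history report for a trial
#'
#' The engine's equivalent of a results screen: for every measure, the by-day
#' and by-phase aggregates and (for numeric measures with data in both phase
#' types) the phase contrast; list measures get per-phase item frequencies.
#' Measures without observations are marked as having no data.
#'
#' @param spec A valid `nof1_trial`.
#' @param log An observation tibble.
#' @param with_test Add Welch t-tests to contrasts where at least two
#'   observations exist per phase type.
#' @return A `nof1_history` object; print it for a text rendering or convert
#'   with [history_to_json()].
#' @export
history_report <- function(spec, log, with_test = FALSE) {
  stop_if_invalid(spec)
  sections <- lapply(spec$measures, function(m) {
    obs <- log[log$measure_id == m$id, , drop = FALSE]
    sec <- list(measure_id = m$id, name = m$name, input_type = m$input_type,
                n_observations = nrow(obs))
    if (nrow(obs) == 0) {
      sec$no_data <- TRUE
      return(sec)
    }
    if (m$input_type == "list") {
      sec$by_day <- list_frequencies(log, spec, m$id, "day")
      sec$by_phase <- list_frequencies(log, spec, m$id, "phase")
    } else {
      sec$by_day <- aggregate_observations(log, spec, m$id, "day")
      sec$by_phase <- aggregate_observations(log, spec, m$id, "phase")
      has_both <- all(c("A", "B") %in% obs$phase_label)
      if (has_both) {
        counts <- table(obs$phase_label)
        testable <- with_test && all(counts[c("A", "B")] >= 2)
        sec$contrast <- phase_contrast(log, spec, m$id, with_test = testable)
      }
    }
    sec
  })
  structure(
    list(
      trial_id = spec$id,
      goal = spec$goal$name,
      design = spec$design,
      measures = sections
    ),
    class = "nof1_history"
  )
}

#' @export
print.nof1_history <- function(x, ...) {
  cat("N-of-1 trial history — goal: ", x$goal, " (", x$design, " design)\n",
      sep = "")
  for (sec in x$measures) {
    cat("\n== ", sec$name, " [", sec$input_type, "] ==\n", sep = "")
    if (isTRUE(sec$no_data)) {
      cat("  no data\n")
      next
    }
    cat("  observations:", sec$n_observations, "\n")
    cat("  by phase:\n")
    print(as.data.frame(sec$by_phase), row.names = FALSE)
    if (!is.null(sec$contrast)) {
      cat(sprintf("  contrast (A - B): %.4g\n", sec$contrast$difference))
      if (!is.null(sec$contrast$statistic)) {
        cat(sprintf("  Welch t = %.4g, df = %.2f, p = %.4g\n",
                    sec$contrast$statistic, sec$contrast$df, sec$contrast$p_value))
      }
    }
  }
  invisible(x)
}

#' Render a history report as JSON
#'
#' @param report A `nof1_history` from [history_report()].
#' @param pretty Indent the output.
#' @return JSON text.
#' @export
history_to_json <- function(report, pretty = TRUE) {
  payload <- list(
    trial_id = report$trial_id,
    goal = report$goal,
    design = report$design,
    measures = lapply(report$measures, function(sec) {
      out <- sec
      if (!is.null(out$by_day)) out$by_day <- as.data.frame(out$by_day)
      if (!is.null(out$by_phase)) out$by_phase <- as.data.frame(out$by_phase)
      if (!is.null(out$contrast)) out$contrast <- unclass(out$contrast)
      out
    })
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = pretty))
}
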