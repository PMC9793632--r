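#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phase contrast
#'
#' One row per contrast in broom convention: `estimate` is the A minus B
#' difference, `statistic`/`parameter`/`p.value` are the Welch t-test results
#' when computed (otherwise `NA`).
#'
#' @param x A `nof1_contrast`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.nof1_contrast <- function(x, ...) {
  tibble::tibble(
    measure_id = x$measure_id,
    mean_A = x$mean_A,
    mean_B = x$mean_B,
    estimate = x$difference,
    n_A = x$n_A,
    n_B = x$n_B,
    statistic = x$statistic %||% NA_real_,
    parameter = x$df %||% NA_real_,
    p.value = x$p_value %||% NA_real_
  )
}

#' @rdname tidy.nof1_contrast
#' @export
glance.nof1_contrast <- function(x, ...) {
  tibble::tibble(
    estimate = x$difference,
    n = x$n_A + x$n_B,
    tested = !is.null(x$statistic)
  )
}

#' Tidy a history report
#'
#' Long tibble of the per-measure phase contrasts in a [history_report()];
#' measures without a contrast (no data, or data in only one phase type)
#' appear with `NA` estimates.
#'
#' @param x A `nof1_history`.
#' @param ... Unused.
#' @return A tibble with one row per measure.
#' @export
tidy.nof1_history <- function(x, ...) {
  dplyr::bind_rows(lapply(x$measures, function(sec) {
    base <- tibble::tibble(
      measure_id = sec$measure_id,
      name = sec$name,
      input_type = sec$input_type,
      n_observations = sec$n_observations
    )
    if (is.null(sec$contrast)) {
      dplyr::mutate(base, mean_A = NA_real_, mean_B = NA_real_,
                    estimate = NA_real_, statistic = NA_real_,
                    parameter = NA_real_, p.value = NA_real_)
    } else {
      dplyr::bind_cols(base, dplyr::select(
        tidy(sec$contrast), -"measure_id", -"n_A", -"n_B"
      ))
    }
  }))
}

#' @rdname tidy.nof1_history
#' @export
glance.nof1_history <- function(x, ...) {
  n_obs <- sum(vapply(x$measures, `[[`, numeric(1), "n_observations"))
  tibble::tibble(
    trial_id = x$trial_id,
    design = x$design,
    n_measures = length(x$measures),
    n_observations = n_obs,
    n_with_data = sum(vapply(x$measures, function(s) s$n_observations > 0, logical(1)))
  )
}
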