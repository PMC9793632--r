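#' Simulation configuration for a synthetic participant
#'
#' States the outcome and adherence model under which observations are
#' generated. Each completed measurement on trial day `t` takes the value
#'
#'   y = baseline + effect(active intervention on day t) + trend * t + noise,
#'
#' with independent Gaussian noise of standard deviation `noise_sd`. On
#' withdrawal no-intervention (B) days the effect term is 0. Every task —
#' intervention or measurement — is completed independently with probability
#' `adherence`; skipped measurement tasks produce no observation and the task
#' is marked missed. Scale-measure values are clipped to `[min, max]` *after*
#' noise, mimicking a bounded instrument.
#'
#' Defaults describe a plausible mildly effective intervention on an
#' instrument with unit-scale noise and the imperfect-but-engaged adherence
#' typical of self-tracking: baseline 5, effect 1, no trend, noise sd 1,
#' adherence 0.9.
#'
#' @param baseline Mean outcome with no intervention (model intercept).
#' @param effect Intervention effect(s): one number per intervention, recycled
#'   to the number of interventions in the trial.
#' @param trend Linear time trend per day (0 = stationary).
#' @param noise_sd Standard deviation of the Gaussian observation noise, `>= 0`.
#' @param adherence Per-task completion probability `q` in `[0, 1]`.
#' @param seed Integer seed making the participant fully reproducible.
#' @param list_measures `"skip"` (list measures yield tasks but no simulated
#'   observations) or `"uniform"` (an item drawn uniformly at random).
#' @return A `nof1_sim_config` list.
#' @export
simulation_config <- function(baseline = 5, effect = 1, trend = 0,
                              noise_sd = 1, adherence = 0.9, seed = 1L,
                              list_measures = c("skip", "uniform")) {
  if (noise_sd < 0) abort_nof1("bad_argument", "noise_sd must be >= 0")
  if (adherence < 0 || adherence > 1) {
    abort_nof1("bad_argument", "adherence must lie in [0, 1]")
  }
  structure(
    list(
      baseline = as.numeric(baseline),
      effect = as.numeric(effect),
      trend = as.numeric(trend),
      noise_sd = as.numeric(noise_sd),
      adherence = as.numeric(adherence),
      seed = as.integer(seed),
      list_measures = match.arg(list_measures)
    ),
    class = "nof1_sim_config"
  )
}

#' Simulate a participant running a trial
#'
#' Generates the full task log and observation log a participant following
#' the stated outcome/adherence model would produce: the task calendar is
#' expanded with [notification_schedule()], each task is completed with
#' probability `adherence`, and each completed measurement task of a numeric
#' measure yields one observation from the outcome model. Identical
#' `(spec, config, start_date)` always yield identical logs.
#'
#' @param spec A valid `nof1_trial` whose measures are numeric (list measures
#'   are handled per `config$list_measures`).
#' @param config A [simulation_config()].
#' @param start_date Trial start date anchoring day 1 (fixed default so runs
#'   are deterministic).
#' @return A list with elements `tasks` (task tibble, statuses resolved) and
#'   `observations` (observation tibble).
#' @examples
#' trial <- nof1_trial(
#'   goal = goal("Improve sleep"),
#'   interventions = list(intervention("Meditation")),
#'   measures = list(measure_keyboard("sleep", unit = "hours", id = "m1"))
#' )
#' run <- simulate_participant(trial, simulation_config(seed = 42))
#' phase_contrast(run$observations, trial, "m1")
#' @export
simulate_participant <- function(spec, config = simulation_config(),
                                 start_date = as.Date("2022-01-01")) {
  stop_if_invalid(spec)
  start_date <- as.Date(start_date)
  tasks <- notification_schedule(spec, start_date)

  # per-day effect of the active intervention (0 on withdrawal B days)
  effects <- rep_len(config$effect, length(spec$interventions))
  dur <- total_duration(spec$schedule)
  labels <- phase_of_day(spec$schedule, seq_len(dur))
  day_effect <- if (spec$design == "withdrawal") {
    ifelse(labels == "A", effects[1], 0)
  } else {
    ifelse(labels == "A", effects[1], effects[2])
  }

  measures <- stats::setNames(spec$measures,
                              vapply(spec$measures, `[[`, character(1), "id"))

  with_preserved_rng(config$seed, {
    done <- stats::runif(nrow(tasks)) < config$adherence
    tasks$status <- ifelse(done, "completed", "missed")
    tasks$completed_at <- ifelse(
      done, paste0(format(tasks$date), "T", tasks$time, ":00"), NA_character_
    )

    obs_rows <- tasks$kind == "measurement" & done
    obs <- tasks[obs_rows, , drop = FALSE]
    type <- vapply(obs$component_id,
                   function(id) measures[[id]]$input_type, character(1))

    numeric_obs <- obs[type != "list", , drop = FALSE]
    values <- character(0)
    if (nrow(numeric_obs) > 0) {
      eps <- stats::rnorm(nrow(numeric_obs), 0, config$noise_sd)
      y <- config$baseline + day_effect[numeric_obs$day_index] +
        config$trend * numeric_obs$day_index + eps
      # bounded instruments clip after noise
      num_type <- type[type != "list"]
      for (k in which(num_type == "scale")) {
        sc <- measures[[numeric_obs$component_id[k]]]$scale_config
        y[k] <- min(max(y[k], sc$min), sc$max)
      }
      values <- vapply(y, format_value, character(1))
    }

    list_obs <- obs[type == "list", , drop = FALSE]
    list_values <- character(0)
    if (nrow(list_obs) > 0 && config$list_measures == "uniform") {
      list_values <- vapply(seq_len(nrow(list_obs)), function(k) {
        items <- measures[[list_obs$component_id[k]]]$list_config$items
        sample(items, 1L)
      }, character(1))
    }

    keep_list <- config$list_measures == "uniform"
    obs_out <- dplyr::bind_rows(
      if (nrow(numeric_obs) > 0) tibble::tibble(
        measure_id = numeric_obs$component_id,
        timestamp = paste0(format(numeric_obs$date), "T", numeric_obs$time, ":00"),
        day_index = numeric_obs$day_index,
        phase_label = numeric_obs$phase_label,
        value = values
      ),
      if (keep_list && nrow(list_obs) > 0) tibble::tibble(
        measure_id = list_obs$component_id,
        timestamp = paste0(format(list_obs$date), "T", list_obs$time, ":00"),
        day_index = list_obs$day_index,
        phase_label = list_obs$phase_label,
        value = list_values
      )
    )
    if (is.null(obs_out)) obs_out <- new_observation_log()
    obs_out <- dplyr::bind_rows(new_observation_log(), obs_out)
    obs_out <- obs_out[order(parse_timestamp(obs_out$timestamp)), , drop = FALSE]

    list(tasks = tasks, observations = obs_out)
  })
}

#' Simulate a cohort of independent participants
#'
#' Runs [simulate_participant()] `n_participants` times with per-participant
#' seeds derived from a master seed through a fixed splittable scheme
#' (`(master * 10007 + i) mod (2^31 - 1)` for participant `i`), so cohorts
#' are reproducible and participants mutually independent.
#'
#' @inheritParams simulate_participant
#' @param n_participants Number of participants, `>= 1`.
#' @param seed Master seed; defaults to the config's seed.
#' @return A list of `n_participants` results, each as from
#'   [simulate_participant()].
#' @export
simulate_cohort <- function(spec, config = simulation_config(), n_participants,
                            seed = config$seed,
                            start_date = as.Date("2022-01-01")) {
  if (!is_count(n_participants, min = 1L)) {
    abort_nof1("bad_argument", "n_participants must be an integer >= 1")
  }
  lapply(seq_len(n_participants), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    simulate_participant(spec, cfg, start_date = start_date)
  })
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 10007 + i) %% 2147483647)
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
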