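# fixtures are built in code: a canonical small trial plus random generators
# used by the property-style tests

make_trial <- function(design = "withdrawal",
                       schedule = default_schedule(),
                       measures = list(measure_keyboard("sleep", unit = "hours", id = "m1")),
                       times = "08:00") {
  interventions <- list(intervention("Meditation", "10 min before bed",
                                     reminder = reminder_policy(times = times),
                                     id = "iv1"))
  if (design == "alternating_treatment") {
    interventions <- c(interventions, list(
      intervention("Evening walk", "30 min walk",
                   reminder = reminder_policy(times = times), id = "iv2")
    ))
  }
  nof1_trial(
    goal = goal("Improve sleep"),
    interventions = interventions,
    measures = measures,
    design = design,
    schedule = schedule,
    id = "trial-1",
    created_at = "2022-01-01T00:00:00"
  )
}

random_hhmm <- function(n) {
  mins <- sort(sample(0:1439, n))
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

random_reminder <- function() {
  times <- random_hhmm(sample(1:3, 1))
  if (runif(1) < 0.5) {
    reminder_policy(times = times)
  } else {
    reminder_policy(times = times, recurrence = "every_x_days",
                    interval_days = sample(2:5, 1))
  }
}

random_measure <- function(id) {
  type <- sample(c("keyboard", "list", "scale"), 1)
  name <- paste0("measure ", id)
  switch(type,
    keyboard = measure_keyboard(name, unit = sample(c("hours", "kg", "steps"), 1),
                                reminder = random_reminder(), id = id),
    list = measure_list(name, items = c("yes", "no", "maybe")[seq_len(sample(2:3, 1))],
                        reminder = random_reminder(), id = id),
    scale = {
      lo <- sample(0:3, 1)
      hi <- lo + sample(5:10, 1)
      measure_scale(name, min = lo, max = hi,
                    annotations = list(list(position = lo, label = "low"),
                                       list(position = hi, label = "high")),
                    reminder = random_reminder(), id = id)
    }
  )
}

random_schedule <- function(max_d = 10, max_p = 5) {
  schedule(sample(seq_len(max_d), 1), sample(seq_len(max_p), 1),
           sample(c("alternating", "counterbalanced"), 1))
}

random_trial_spec <- function(max_d = 10, max_p = 5) {
  design <- sample(c("withdrawal", "alternating_treatment"), 1)
  n_iv <- if (design == "withdrawal") 1L else 2L
  interventions <- lapply(seq_len(n_iv), function(k) {
    intervention(paste0("intervention ", k), "do the thing",
                 reminder = random_reminder(), id = paste0("iv", k))
  })
  measures <- lapply(seq_len(sample(1:3, 1)), function(k) {
    random_measure(paste0("m", k))
  })
  nof1_trial(
    goal = goal("a goal", rationale = if (runif(1) < 0.5) "because" else NULL),
    interventions = interventions,
    measures = measures,
    design = design,
    schedule = random_schedule(max_d, max_p),
    id = paste0("trial-", sample.int(1e6, 1)),
    created_at = "2022-01-01T12:00:00"
  )
}

# corrupt a valid spec in one known way; returns list(spec, code)
random_invalid_spec <- function() {
  spec <- random_trial_spec()
  breakers <- list(
    function(s) { s$interventions <- s$interventions[1]; s$design <- "alternating_treatment"
                  list(s, "design_interventions_mismatch") },
    function(s) { s$measures <- list(); list(s, "missing_component") },
    function(s) { s$goal$name <- ""; list(s, "empty_name") },
    function(s) { s$measures[[1]] <- measure_scale("bad", min = 10, max = 1, id = "mx")
                  list(s, "scale_range") },
    function(s) { s$measures[[1]]$reminder <- NULL; list(s, "reminder_missing") },
    function(s) { s$measures[[1]]$reminder <- reminder_policy(times = c("10:00", "09:00"))
                  list(s, "reminder_times") },
    function(s) { s$schedule$n_phase_pairs <- 0L; list(s, "schedule_phase_pairs") },
    function(s) { s$interventions[[1]]$reminder <-
                    list(times = "08:00", recurrence = "every_x_days", interval_days = 1L)
                  list(s, "reminder_interval") }
  )
  breakers[[sample(length(breakers), 1)]](spec)
}

# textbook Welch statistic, independent of stats::t.test
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
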