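#' Load the preconfigured component library
#'
#' The engine ships editable goal, intervention and measure templates plus
#' goal-to-intervention links, so a trial can be assembled from vetted
#' examples rather than written from scratch. Four goals (reduce back pain,
#' treat leg cramps, treat rheumatoid arthritis, treat irritable bowel
#' syndrome) each link to three suggested interventions; the remaining
#' entries are general examples. The library lives in a JSON data file using
#' the same dialect as trial components, so it can be extended without code
#' changes.
#'
#' @param path Library JSON file; defaults to the packaged one.
#' @return A `nof1_library` list with elements `goals`, `interventions`,
#'   `measures` (lists of templates, without ids) and `links` (named list
#'   mapping goal name to suggested intervention names).
#' @export
component_library <- function(path = system.file("extdata", "component_library.json",
                                                 package = "nof1engine")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lib <- structure(
    list(
      goals = lapply(raw$goals, rebuild_goal),
      interventions = lapply(raw$interventions, function(i) {
        out <- rebuild_intervention(i)
        out$id <- NULL  # templates get ids at instantiation
        out
      }),
      measures = lapply(raw$measures, function(m) {
        out <- rebuild_measure(m)
        out$id <- NULL
        out
      }),
      links = lapply(raw$links, chr_vec)
    ),
    class = "nof1_library"
  )
  iv_names <- vapply(lib$interventions, `[[`, character(1), "name")
  missing <- setdiff(unlist(lib$links, use.names = FALSE), iv_names)
  if (length(missing) > 0) {
    abort_nof1("library_integrity", paste0(
      "library links reference unknown intervention(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  lib
}

#' Suggested interventions for a goal
#'
#' Returns the library's intervention templates ordered for a given goal:
#' the interventions linked to that goal come first (in their linked order),
#' followed by the remaining general library entries. Unknown goals simply
#' get the general list.
#'
#' @param goal_name Goal name to look up (matched case-insensitively).
#' @param library A [component_library()].
#' @return A list of intervention templates.
#' @examples
#' s <- suggestions_for_goal("Reduce back pain")
#' vapply(s[1:3], `[[`, character(1), "name")
#' @export
suggestions_for_goal <- function(goal_name, library = component_library()) {
  names_lc <- tolower(names(library$links))
  hit <- match(tolower(goal_name), names_lc)
  iv_names <- vapply(library$interventions, `[[`, character(1), "name")
  if (is.na(hit)) {
    return(library$interventions)
  }
  linked <- library$links[[hit]]
  idx <- c(match(linked, iv_names), setdiff(seq_along(iv_names), match(linked, iv_names)))
  library$interventions[idx]
}

#' Instantiate a library template
#'
#' Produces an editable copy of a template, detached from the library:
#' interventions and measures receive a fresh id, and later edits to the copy
#' never affect the library entry (R's copy-on-modify semantics guarantee
#' this; the function makes the intent explicit and adds the id).
#'
#' @param template A goal, intervention or measure template from a
#'   [component_library()].
#' @return A component usable in [nof1_trial()].
#' @export
instantiate_template <- function(template) {
  out <- template
  # goals carry no id; interventions and measures do
  if (!is.null(out$input_type) || !is.null(out$reminder)) {
    out$id <- new_id()
    # keep canonical field order (id first) so instantiated components
    # serialize identically to constructor-built ones
    first <- intersect(c("id", "name", "instructions", "input_type",
                         "keyboard_config", "list_config", "scale_config",
                         "reminder"), names(out))
    out <- out[first]
  }
  out
}

#' @export
print.nof1_library <- function(x, ...) {
  cat("<nof1_library> ", length(x$goals), " goals, ", length(x$interventions),
      " interventions, ", length(x$measures), " measures\n", sep = "")
  cat("  linked goals: ", paste(names(x$links), collapse = "; "), "\n", sep = "")
  invisible(x)
}
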