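#' Specify a what-if scenario
#'
#' A scenario activates a subset of concepts at initial levels in
#' \eqn{[0, 1]} and leaves every other concept at 0. The outcome concept
#' (homelessness in the packaged map) is never pre-activated: scenarios ask
#' what the activated factors *do* to it.
#'
#' @param activations Named numeric vector of initial values in \eqn{[0, 1]}.
#' @param label Short name for reports.
#' @param settings An `fcm_settings`; defaults to the tanh case-study
#'   configuration (`self_memory = 1`, no clamping, `epsilon = 1e-5`,
#'   `max_iter = 100`).
#' @param outcome Name of the outcome concept (default `"Homelessness"`).
#' @return An object of class `fcm_scenario`.
#' @export
scenario_spec <- function(activations, label = "scenario",
                          settings = simulation_settings("tanh"),
                          outcome = "Homelessness") {
  stopifnot(is.numeric(activations), !is.null(names(activations)))
  if (any(activations < 0 | activations > 1)) {
    stop("activation outside [0, 1]: ",
         names(activations)[which(activations < 0 | activations > 1)[1]],
         call. = FALSE)
  }
  nm <- normalize_concept(names(activations))
  if (tolower(outcome) %in% tolower(nm)) {
    stop("the outcome concept must not be pre-activated", call. = FALSE)
  }
  structure(
    list(activations = stats::setNames(as.numeric(activations), nm),
         label = label, settings = settings, outcome = outcome),
    class = "fcm_scenario"
  )
}

#' @export
print.fcm_scenario <- function(x, ...) {
  cat(sprintf("<fcm_scenario> '%s': %s\n", x$label,
              paste(sprintf("%s=%.2f", names(x$activations), x$activations),
                    collapse = ", ")))
  invisible(x)
}

#' Run a scenario and classify its outcome
#'
#' Simulates the map from the scenario's activations and classifies the
#' final level `h` of the outcome concept: `h >= likely` is
#' `"likely_homelessness"`, `h <= unlikely` is `"unlikely_homelessness"`,
#' anything between is `"uncertain"`. The default cutoffs 0.9 / 0.1 mirror
#' the saturated-versus-near-zero trajectories that separate the extreme
#' prototypical cases.
#'
#' @param map A `concept_map` containing the scenario's concepts.
#' @param spec An `fcm_scenario`.
#' @param likely,unlikely Classification cutoffs on the final outcome level.
#' @return A list of class `fcm_case` with elements `trace` (an
#'   `fcm_trace`) and `outcome` (a one-row tibble: `label`, `category`,
#'   `final_level`, `termination`, `n_states`).
#' @examples
#' fcm <- weight_matrix(homelessness_kb())
#' res <- run_case(fcm, homelessness_cases()[[1]])
#' res$outcome
#' @export
run_case <- function(map, spec, likely = 0.9, unlikely = 0.1) {
  stopifnot(inherits(map, "concept_map"), inherits(spec, "fcm_scenario"))
  outcome_name <- normalize_concept(spec$outcome, map$concepts)
  if (!outcome_name %in% map$concepts) {
    stop("outcome concept '", spec$outcome, "' not in map", call. = FALSE)
  }
  trace <- fcm_simulate(map, spec$activations, spec$settings)
  h <- trace$states[nrow(trace$states), outcome_name]
  category <- if (h >= likely) {
    "likely_homelessness"
  } else if (h <= unlikely) {
    "unlikely_homelessness"
  } else {
    "uncertain"
  }
  outcome <- tibble::tibble(
    label = spec$label,
    category = category,
    final_level = unname(h),
    termination = trace$termination,
    n_states = nrow(trace$states)
  )
  structure(list(trace = trace, outcome = outcome,
                 summary = trajectory_summary(trace)),
            class = "fcm_case")
}

#' @export
print.fcm_case <- function(x, ...) {
  cat(sprintf("<fcm_case> '%s': %s (final level %.4f, %s after %d states)\n",
              x$outcome$label, x$outcome$category, x$outcome$final_level,
              x$outcome$termination, x$outcome$n_states))
  invisible(x)
}

#' Per-concept trajectory summary
#'
#' @param trace An `fcm_trace`.
#' @return Tibble with `concept`, `min`, `max`, `final`.
#' @export
trajectory_summary <- function(trace) {
  stopifnot(inherits(trace, "fcm_trace"))
  tibble::tibble(
    concept = colnames(trace$states),
    min = apply(trace$states, 2, min),
    max = apply(trace$states, 2, max),
    final = trace$states[nrow(trace$states), ]
  )
}

#' Order scenario outcomes by final outcome level
#'
#' @param results A list of `fcm_case` objects (or of their `outcome`
#'   tibbles).
#' @return Tibble ordered by decreasing `final_level` with a `rank` column;
#'   exact ties share a rank and are flagged in `tied`.
#' @export
compare_cases <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- purrr::map(results, function(r) {
    if (inherits(r, "fcm_case")) r$outcome else tibble::as_tibble(r)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$final_level))
  out$rank <- rank(-out$final_level, ties.method = "min")
  out$tied <- duplicated(out$final_level) |
    duplicated(out$final_level, fromLast = TRUE)
  out
}
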