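#' Packaged evidence base of the homelessness map
#'
#' The linguistic knowledge base behind the packaged fuzzy cognitive map of
#' homelessness: 14 concepts and 31 directed influences, each supported by
#' three linguistic statements harvested from peer-reviewed empirical
#' studies and graded on the five-level ordinal scale (93 terms in all).
#' The `refs` column carries the citation tags of the supporting studies;
#' one influence (Addiction on Family Breakdown) cites the same study twice
#' with two distinct phrasings, and both gradings are kept as recorded.
#'
#' @return An `fcm_kb` object.
#' @examples
#' kb <- homelessness_kb()
#' evidence_counts(kb)
#' @export
homelessness_kb <- function() {
  read_knowledge_base(
    system.file("extdata", "homelessness_knowledge_base.csv",
                package = "socialfcm", mustWork = TRUE),
    concepts = homelessness_concepts()
  )
}

#' Packaged word bank of graded linguistic terms
#'
#' The closed lexicon mapping the phrases encountered during the literature
#' scan to ordinal levels. A handful of phrases were recorded under two
#' levels by different raters ("most effective", "statistically
#' significant"); the packaged lexicon keeps the first listing, scanning
#' levels from Very Low upward.
#'
#' @return An `fcm_lexicon` object.
#' @export
homelessness_lexicon <- function() {
  read_lexicon(
    system.file("extdata", "term_lexicon.csv",
                package = "socialfcm", mustWork = TRUE),
    multiple = "first"
  )
}

#' The FIS-weighted homelessness map
#'
#' Convenience wrapper: [homelessness_kb()] pushed through
#' [weight_matrix()] with the given partition.
#'
#' @param partition An `fcm_partition`.
#' @return A `concept_map` with 14 concepts and 31 signed weighted edges.
#' @export
homelessness_map <- function(partition = fuzzy_partition()) {
  weight_matrix(homelessness_kb(), partition)
}

#' Six-concept heart-disease demonstration map
#'
#' The small worked example used to introduce sign-mode FCM processing:
#' Exercise, Food Habits, Cholesterol, Body Weight, Blood Pressure, and
#' Heart Disease, with weights in \eqn{\{-1, 0, 1\}}. The diagonal is stored
#' as printed (1 for all concepts except Heart Disease); it never enters the
#' update sum, where self-influence is governed by the `self_memory`
#' setting.
#'
#' @return A `concept_map`.
#' @examples
#' hd <- heart_disease_map()
#' fcm_simulate(hd, c(Exercise = 1),
#'   simulation_settings("sign", clamp = c(Exercise = 1)))
#' @export
heart_disease_map <- function() {
  read_adjacency_matrix(
    system.file("extdata", "heart_disease_map.csv",
                package = "socialfcm", mustWork = TRUE)
  )
}

#' The three prototypical homelessness scenarios
#'
#' The packaged what-if cases: an extreme case most likely to result in
#' homelessness (addiction, family breakdown, government assistance and
#' mental illness all activated around 0.5-0.65), an extreme case least
#' likely (strong education, income and social support against moderate
#' addiction), and a middle case with an uncertain outcome.
#'
#' @param path Optional path to a scenario JSON file with the same schema as
#'   the packaged one: a `cases` array (each with `label` + `activations`),
#'   a shared `settings` block (`threshold`, `epsilon`, `max_iter`,
#'   `self_memory`, optional `clamp` object), and an optional top-level
#'   `outcome` concept name (default `"Homelessness"`).
#' @return A list of `fcm_scenario` objects.
#' @export
homelessness_cases <- function(path = NULL) {
  path <- path %||% system.file("extdata", "homelessness_cases.json",
                                package = "socialfcm", mustWork = TRUE)
  cfg <- jsonlite::read_json(path)
  st <- cfg$settings %||% list()
  clamp <- if (length(st$clamp)) unlist(st$clamp) else NULL
  settings <- simulation_settings(
    threshold = st$threshold %||% "tanh",
    epsilon = st$epsilon %||% 1e-5,
    max_iter = st$max_iter %||% 100,
    clamp = clamp,
    self_memory = st$self_memory %||%
      (if ((st$threshold %||% "tanh") == "sign") 0 else 1)
  )
  outcome <- cfg$outcome %||% "Homelessness"
  lapply(cfg$cases, function(cs) {
    scenario_spec(unlist(cs$activations), label = cs$label,
                  settings = settings, outcome = outcome)
  })
}
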