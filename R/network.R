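#' Settings for centrality computations
#'
#' Distances between connected concepts are the inverse of the absolute edge
#' weight, \eqn{d_{xy} = 1/|w_{xy}|}. Pairs with no directed path are
#' assigned the Big-M penalty, a constant chosen to dominate any finite path
#' length: with N concepts and a minimum weight magnitude of 0.25 the longest
#' possible path is 4(N-1) (52 for the packaged 14-concept map), so the
#' default 100 is safely "infinite". Raising Big-M changes closeness values
#' but not their ranking.
#'
#' @param big_m Penalty distance for unreachable pairs (default 100).
#' @param include_self_loops Whether diagonal entries count towards degree
#'   centrality (default `FALSE`).
#' @param report_scale Multiplier applied to raw closeness for display
#'   (default `1e4`; raw values are of order 1e-3).
#' @return A list of class `fcm_centrality_settings`.
#' @export
centrality_settings <- function(big_m = 100, include_self_loops = FALSE,
                                report_scale = 1e4) {
  stopifnot(big_m > 0)
  structure(list(big_m = big_m, include_self_loops = include_self_loops,
                 report_scale = report_scale),
            class = "fcm_centrality_settings")
}

#' Degree centrality of every concept
#'
#' Sum of the absolute weights of all outgoing and incoming edges,
#' \eqn{\sum_y |w_{xy}| + |w_{yx}|}. Self-loops are excluded unless the
#' settings say otherwise. Flipping the sign of any edge leaves degree
#' centrality unchanged.
#'
#' @param map A `concept_map`.
#' @param settings An `fcm_centrality_settings`.
#' @return Tibble with columns `concept`, `degree`.
#' @export
degree_centrality <- function(map, settings = centrality_settings()) {
  stopifnot(inherits(map, "concept_map"))
  W <- abs(map$W)
  if (!settings$include_self_loops) diag(W) <- 0
  tibble::tibble(
    concept = map$concepts,
    degree = unname(rowSums(W) + colSums(W))
  )
}

#' All-pairs shortest-path distances under inverse-weight lengths
#'
#' Each edge gets length \eqn{1/|w|}; shortest directed path lengths are
#' computed on true infinities first, and the Big-M penalty is substituted
#' for unreachable pairs only afterwards (so Big-M can never occur inside a
#' multi-hop path). The diagonal is 0.
#'
#' @param map A `concept_map`.
#' @param settings An `fcm_centrality_settings`.
#' @return An N-by-N numeric matrix of distances.
#' @export
concept_distances <- function(map, settings = centrality_settings()) {
  stopifnot(inherits(map, "concept_map"))
  el <- tidy(map)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$source, to = el$target,
               weight = 1 / abs(el$weight)),
    directed = TRUE,
    vertices = data.frame(name = map$concepts)
  )
  D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  D <- D[map$concepts, map$concepts, drop = FALSE]
  D[is.infinite(D)] <- settings$big_m
  diag(D) <- 0
  D
}

#' Closeness centrality of every concept
#'
#' Inverse of the summed shortest-path distances from a concept to all
#' others, \eqn{1 / \sum_{y \ne x} d_{xy}}, with unreachable pairs priced at
#' Big-M. A scaled copy (`closeness_scaled`, default \eqn{\times 10^4}) is
#' reported alongside the raw value.
#'
#' @param map A `concept_map`.
#' @param settings An `fcm_centrality_settings`.
#' @return Tibble with columns `concept`, `closeness_raw`,
#'   `closeness_scaled`. For a single-concept map the sum of distances is
#'   empty; the closeness is reported as `Inf` with a warning (degenerate).
#' @export
closeness_centrality <- function(map, settings = centrality_settings()) {
  D <- concept_distances(map, settings)
  n <- nrow(D)
  if (n == 1) {
    warning("single-concept map: closeness centrality is degenerate")
    total <- 0
  } else {
    total <- rowSums(D)
  }
  raw <- 1 / total
  tibble::tibble(
    concept = map$concepts,
    closeness_raw = unname(raw),
    closeness_scaled = unname(raw * settings$report_scale)
  )
}

#' Full centrality report
#'
#' @param map A `concept_map`.
#' @param settings An `fcm_centrality_settings`.
#' @return Tibble with `concept`, `degree`, `closeness_raw`,
#'   `closeness_scaled`.
#' @examples
#' centrality_report(weight_matrix(homelessness_kb()))
#' @export
centrality_report <- function(map, settings = centrality_settings()) {
  dplyr::left_join(
    degree_centrality(map, settings),
    closeness_centrality(map, settings),
    by = "concept"
  )
}

#' One-at-a-time sensitivity sweep of a concept
#'
#' Varies the initial value of a single concept over `grid` while every other
#' concept (except the outcome) starts at a small common `baseline`, runs a
#' fixed number of tanh updates, and records the outcome concept's value.
#' The outcome concept itself always starts at 0. The short horizon and low
#' baseline keep the system away from saturation so that the swept concept's
#' influence is visible.
#'
#' @param map A `concept_map`.
#' @param concept Concept to sweep (not the outcome).
#' @param grid Initial values to try (default `seq(0.1, 1, by = 0.1)`).
#' @param baseline Common initial value for all other concepts (default
#'   0.01).
#' @param iterations Number of tanh updates before reading off the outcome
#'   (default 3).
#' @param outcome Outcome concept name (default `"Homelessness"`).
#' @param settings An `fcm_settings` used for the updates (tanh,
#'   `self_memory = 1` by default); its `max_iter` is ignored in favour of
#'   `iterations`.
#' @return A tibble of class `fcm_sweep` with columns `concept`, `initial`,
#'   `outcome_value`; the baseline, iteration count and outcome name are
#'   attached as attributes.
#' @export
sensitivity_sweep <- function(map, concept,
                              grid = seq(0.1, 1, by = 0.1),
                              baseline = 0.01, iterations = 3,
                              outcome = "Homelessness",
                              settings = simulation_settings("tanh")) {
  stopifnot(inherits(map, "concept_map"), all(diff(grid) > 0))
  concept <- normalize_concept(concept, map$concepts)
  outcome <- normalize_concept(outcome, map$concepts)
  if (!concept %in% map$concepts) stop("unknown concept: ", concept,
                                       call. = FALSE)
  if (!outcome %in% map$concepts) stop("unknown outcome concept: ", outcome,
                                       call. = FALSE)
  if (concept == outcome) stop("cannot sweep the outcome concept",
                               call. = FALSE)
  run <- simulation_settings(settings$threshold, settings$epsilon,
                             max_iter = iterations, clamp = settings$clamp,
                             self_memory = settings$self_memory)
  vals <- purrr::map_dbl(grid, function(v) {
    A <- stats::setNames(rep(baseline, length(map$concepts)), map$concepts)
    A[outcome] <- 0
    A[concept] <- v
    tr <- fcm_simulate(map, A, run)
    # read the state after exactly `iterations` updates, converged or not
    tr$states[min(nrow(tr$states), iterations + 1L), outcome]
  })
  out <- tibble::tibble(concept = concept, initial = grid,
                        outcome_value = vals)
  class(out) <- c("fcm_sweep", class(out))
  attr(out, "baseline") <- baseline
  attr(out, "iterations") <- iterations
  attr(out, "outcome") <- outcome
  out
}

#' Quartile summary of sensitivity sweeps
#'
#' Box-plot statistics of each swept concept's outcome values: minimum,
#' lower quartile, median, upper quartile, maximum and interquartile range
#' (quantile type 7). A wide box means the outcome depends strongly on where
#' the concept starts, i.e. the concept is a *variable*, not a dominant,
#' influence.
#'
#' @param results An `fcm_sweep` tibble or a list of them.
#' @return Tibble with one row per concept: `concept`, `min`, `q1`, `median`,
#'   `q3`, `max`, `iqr`.
#' @export
sweep_summary <- function(results) {
  if (inherits(results, "fcm_sweep")) results <- list(results)
  stopifnot(length(results) >= 1)
  dplyr::bind_rows(lapply(results, tibble::as_tibble)) |>
    dplyr::group_by(.data$concept) |>
    dplyr::summarise(
      min = min(.data$outcome_value),
      q1 = stats::quantile(.data$outcome_value, 0.25, names = FALSE),
      median = stats::median(.data$outcome_value),
      q3 = stats::quantile(.data$outcome_value, 0.75, names = FALSE),
      max = max(.data$outcome_value),
      iqr = .data$q3 - .data$q1,
      .groups = "drop"
    )
}
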