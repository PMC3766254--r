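# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random signed weighted concept map
#'
#' Draws a random directed map with the structural features the analysis
#' assumes: no self-edges, weight magnitudes bounded away from 0 and 1, a
#' configurable fraction of inhibiting edges, and optionally a designated
#' sink concept with no outgoing edges (an outcome-only node, mimicking the
#' role of homelessness). Generation is bit-reproducible for a fixed seed
#' and leaves the caller's RNG state untouched.
#'
#' @param n_concepts Number of concepts (>= 2).
#' @param density Fraction of admissible ordered pairs that carry an edge,
#'   in (0, 1]; the realized edge count is `round(density * n_admissible)`
#'   and must be at least 1.
#' @param weight_range Interval for weight magnitudes, a sub-interval of
#'   (0, 1]; default `c(0.25, 1)`, the range spanned by the five-level
#'   fuzzy partition's defuzzified outputs.
#' @param negative_fraction Expected fraction of negative edges.
#' @param sink_concept If `TRUE`, concept 1 gets no outgoing edges.
#' @param seed Integer seed.
#' @return A `concept_map`; the sink concept's name (or `NA`) is attached as
#'   attribute `"sink"`, the seed as `"seed"`.
#' @examples
#' m <- random_map(8, density = 0.2, seed = 7)
#' glance(m)
#' @export
random_map <- function(n_concepts, density = 0.2,
                       weight_range = c(0.25, 1),
                       negative_fraction = 0.3,
                       sink_concept = TRUE, seed = 1) {
  stopifnot(n_concepts >= 2, density > 0, density <= 1,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] <= 1, weight_range[1] <= weight_range[2],
            negative_fraction >= 0, negative_fraction <= 1)
  concepts <- paste0("C", seq_len(n_concepts))
  pairs <- expand.grid(source = seq_len(n_concepts),
                       target = seq_len(n_concepts))
  pairs <- pairs[pairs$source != pairs$target, ]
  if (sink_concept) pairs <- pairs[pairs$source != 1, ]
  n_edges <- round(density * nrow(pairs))
  if (n_edges < 1) {
    stop("density too low: would generate no edges", call. = FALSE)
  }
  with_rng(seed, {
    pick <- pairs[sample.int(nrow(pairs), n_edges), ]
    w <- stats::runif(n_edges, weight_range[1], weight_range[2])
    s <- ifelse(stats::runif(n_edges) < negative_fraction, -1, 1)
    W <- matrix(0, n_concepts, n_concepts,
                dimnames = list(concepts, concepts))
    W[cbind(pick$source, pick$target)] <- s * w
    out <- concept_map(W, concepts)
    attr(out, "sink") <- if (sink_concept) concepts[1] else NA_character_
    attr(out, "seed") <- seed
    out
  })
}

#' Generate random linguistic evidence
#'
#' Draws edges over the given concepts with three levels each, uniform over
#' the five-level scale, and Bernoulli signs. Useful for exercising the
#' fuzzy inference stage on inputs it has never seen.
#'
#' @param n_edges Number of evidence edges (>= 0).
#' @param seed Integer seed.
#' @param concepts Concept name pool (defaults to enough `"C1"`, `"C2"`, ...
#'   to host the edges); distinct source/target pairs are drawn without
#'   replacement.
#' @param negative_fraction Probability an edge is inhibiting.
#' @return An `fcm_kb` with `n_edges` edges (so `3 * n_edges` linguistic
#'   terms); the seed is attached as attribute `"seed"`.
#' @export
random_evidence <- function(n_edges, seed = 1, concepts = NULL,
                            negative_fraction = 0.3) {
  stopifnot(n_edges >= 0)
  if (is.null(concepts)) {
    concepts <- paste0("C", seq_len(max(2, ceiling(sqrt(n_edges)) + 1)))
  }
  n <- length(concepts)
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  if (n_edges > nrow(pairs)) {
    stop("not enough concept pairs for ", n_edges, " distinct edges",
         call. = FALSE)
  }
  with_rng(seed, {
    pick <- pairs[sample.int(nrow(pairs), n_edges), ]
    edges <- tibble::tibble(
      source = concepts[pick$source],
      target = concepts[pick$target],
      sign = ifelse(stats::runif(n_edges) < negative_fraction, -1, 1),
      level1 = sample(fcm_levels, n_edges, replace = TRUE),
      level2 = sample(fcm_levels, n_edges, replace = TRUE),
      level3 = sample(fcm_levels, n_edges, replace = TRUE)
    )
    out <- knowledge_base(edges, concepts)
    attr(out, "seed") <- seed
    out
  })
}

#' Generate a random scenario over a map
#'
#' Activates a uniform random subset of non-outcome concepts at uniform
#' levels in \eqn{[0, 1]}.
#'
#' @param map A `concept_map`.
#' @param n_active Number of concepts to activate (< number of concepts).
#' @param seed Integer seed.
#' @param outcome Outcome concept excluded from activation; defaults to the
#'   map's `"sink"` attribute, else its first concept.
#' @return An `fcm_scenario`; the seed is attached as attribute `"seed"`.
#' @export
random_scenario <- function(map, n_active, seed = 1, outcome = NULL) {
  stopifnot(inherits(map, "concept_map"))
  outcome <- outcome %||% attr(map, "sink") %||% map$concepts[1]
  if (is.na(outcome)) outcome <- map$concepts[1]
  pool <- setdiff(map$concepts, outcome)
  if (n_active > length(pool)) {
    stop("n_active must be smaller than the number of non-outcome concepts",
         call. = FALSE)
  }
  with_rng(seed, {
    who <- sample(pool, n_active)
    spec <- scenario_spec(
      stats::setNames(stats::runif(n_active), who),
      label = sprintf("random scenario (seed %d)", seed),
      outcome = outcome
    )
    attr(spec, "seed") <- seed
    spec
  })
}
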