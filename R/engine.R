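#' Trivalent sign threshold
#'
#' \eqn{f(x) = -1} for \eqn{x < 0}, \eqn{0} at \eqn{x = 0}, \eqn{+1} for
#' \eqn{x > 0}. Used to bound sign-mode state vectors to \eqn{\{-1, 0, 1\}}.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector in \eqn{\{-1, 0, 1\}}.
#' @export
threshold_sign <- function(x) {
  sign(x)
}

#' Hyperbolic-tangent threshold
#'
#' \eqn{\tanh(x) = (e^{2x} - 1) / (e^{2x} + 1)}, squashing activations into
#' \eqn{(-1, 1)} while preserving order and sign. Used for the weighted-map
#' case studies where graded concept levels matter.
#'
#' @param x Numeric vector.
#' @return Numeric vector in \eqn{(-1, 1)}.
#' @export
threshold_tanh <- function(x) {
  tanh(x)
}

#' Simulation settings for FCM iteration
#'
#' @param threshold `"tanh"` (default) or `"sign"`.
#' @param epsilon Convergence tolerance for tanh mode: iteration stops when
#'   every concept moves by at most `epsilon` in one step. Ignored in sign
#'   mode, which uses exact state repetition.
#' @param max_iter Maximum number of state updates.
#' @param clamp Named numeric vector of concepts held fixed at the given
#'   values after every update (a sustained input). Default none.
#' @param self_memory 0 or 1: weight of a concept's own previous activation
#'   in its update sum. The printed sign-mode worked example is consistent
#'   with `self_memory = 0` plus clamping of the driving concept; the tanh
#'   case studies use `self_memory = 1` with no clamping so activated
#'   concepts can evolve.
#' @return A list of class `fcm_settings`.
#' @export
simulation_settings <- function(threshold = c("tanh", "sign"),
                                epsilon = 1e-5,
                                max_iter = 100,
                                clamp = NULL,
                                self_memory = if (match.arg(threshold) == "sign") 0 else 1) {
  threshold <- match.arg(threshold)
  stopifnot(epsilon > 0, max_iter >= 1, self_memory %in% c(0, 1))
  if (!is.null(clamp)) {
    stopifnot(is.numeric(clamp), !is.null(names(clamp)))
  }
  structure(
    list(threshold = threshold, epsilon = epsilon,
         max_iter = as.integer(max_iter), clamp = clamp,
         self_memory = self_memory),
    class = "fcm_settings"
  )
}

.resolve_state <- function(map, initial) {
  n <- length(map$concepts)
  if (is.null(initial)) return(stats::setNames(numeric(n), map$concepts))
  if (!is.null(names(initial)) && !all(names(initial) == "")) {
    nm <- normalize_concept(names(initial), map$concepts)
    bad <- setdiff(nm, map$concepts)
    if (length(bad) > 0) stop("unknown concept: ", bad[1], call. = FALSE)
    state <- stats::setNames(numeric(n), map$concepts)
    state[nm] <- as.numeric(initial)
    return(state)
  }
  if (length(initial) != n) {
    stop(sprintf("state length %d does not match map size %d",
                 length(initial), n), call. = FALSE)
  }
  stats::setNames(as.numeric(initial), map$concepts)
}

#' One synchronous FCM update
#'
#' Computes, for each concept \eqn{i}, the raw activation
#' \eqn{\sum_{j \ne i} A_j W_{ji} + m A_i} (with `m` the self-memory
#' setting), applies the threshold function, then overwrites any clamped
#' concepts with their clamp values.
#'
#' @param state Numeric state vector (optionally named by concept).
#' @param map A `concept_map`.
#' @param settings An `fcm_settings`.
#' @return List with `raw` (pre-threshold sums) and `state` (the next,
#'   thresholded and clamped, state vector).
#' @export
fcm_step <- function(state, map, settings = simulation_settings()) {
  stopifnot(inherits(map, "concept_map"), inherits(settings, "fcm_settings"))
  A <- .resolve_state(map, state)
  W <- map$W
  diag(W) <- 0  # stored diagonal never enters the sum
  raw <- drop(A %*% W) + settings$self_memory * A
  f <- switch(settings$threshold, sign = threshold_sign, tanh = threshold_tanh)
  nxt <- f(raw)
  if (!is.null(settings$clamp)) {
    nm <- normalize_concept(names(settings$clamp), map$concepts)
    bad <- setdiff(nm, map$concepts)
    if (length(bad) > 0) stop("clamped concept not in map: ", bad[1],
                              call. = FALSE)
    nxt[nm] <- as.numeric(settings$clamp)
  }
  list(raw = raw, state = nxt)
}

#' Iterate an FCM to steady state, limit cycle, or iteration cap
#'
#' Repeats [fcm_step()] from `initial` until one of: (a) in tanh mode, no
#' concept moves by more than `epsilon` (`"converged"`); (b) in sign mode,
#' the new state exactly equals the immediately preceding state
#' (`"converged"`, a fixed point) or an earlier one (`"limit_cycle"`, with
#' its period); or (c) `max_iter` updates have been taken (`"max_iter"`).
#' Sign-mode state space is finite (at most \eqn{3^N} vectors), so with a
#' large enough `max_iter` sign mode always ends in (a fixed point or) a
#' cycle.
#'
#' @param map A `concept_map`.
#' @param initial Initial state: full numeric vector or named activations
#'   (unnamed concepts start at 0).
#' @param settings An `fcm_settings`.
#' @return An `fcm_trace`: list with `states` (matrix, one row per state
#'   vector including the initial one), `raw` (matrix of pre-threshold sums,
#'   one row per update), `termination` (`"converged"`, `"limit_cycle"`, or
#'   `"max_iter"`), `period` (cycle length, `NA` unless a limit cycle), and
#'   `settings`.
#' @examples
#' hd <- heart_disease_map()
#' tr <- fcm_simulate(hd, c(Exercise = 1),
#'   simulation_settings("sign", clamp = c(Exercise = 1)))
#' tr$states
#' @export
fcm_simulate <- function(map, initial, settings = simulation_settings()) {
  stopifnot(inherits(map, "concept_map"), inherits(settings, "fcm_settings"))
  A <- .resolve_state(map, initial)
  n <- length(A)
  states <- matrix(A, nrow = 1, dimnames = list(NULL, map$concepts))
  raws <- matrix(numeric(0), ncol = n, dimnames = list(NULL, map$concepts))
  termination <- "max_iter"
  period <- NA_integer_
  seen <- new.env(hash = TRUE, parent = emptyenv())
  skey <- function(s) paste(s, collapse = ",")
  if (settings$threshold == "sign") assign(skey(A), 1L, envir = seen)

  for (k in seq_len(settings$max_iter)) {
    stp <- fcm_step(A, map, settings)
    if (any(!is.finite(stp$state))) {
      stop("non-finite activation at step ", k, call. = FALSE)
    }
    raws <- rbind(raws, stp$raw)
    states <- rbind(states, stp$state)
    nxt <- stp$state
    if (settings$threshold == "tanh") {
      if (max(abs(nxt - A)) <= settings$epsilon) {
        termination <- "converged"
        A <- nxt
        break
      }
    } else {
      key <- skey(nxt)
      prev <- get0(key, envir = seen)
      if (!is.null(prev)) {
        p <- (k + 1L) - prev
        if (p == 1L) {
          termination <- "converged"
        } else {
          termination <- "limit_cycle"
          period <- p
        }
        A <- nxt
        break
      }
      assign(key, k + 1L, envir = seen)
    }
    A <- nxt
  }
  structure(
    list(states = states, raw = raws, termination = termination,
         period = period, settings = settings),
    class = "fcm_trace"
  )
}

#' @export
print.fcm_trace <- function(x, ...) {
  cat(sprintf("<fcm_trace> %d state vectors, termination: %s%s\n",
              nrow(x$states), x$termination,
              if (!is.na(x$period)) sprintf(" (period %d)", x$period) else ""))
  invisible(x)
}

#' @export
tidy.fcm_trace <- function(x, ...) {
  tibble::as_tibble(x$states) |>
    dplyr::mutate(step = seq_len(nrow(x$states)) - 1L, .before = 1) |>
    tidyr::pivot_longer(-"step", names_to = "concept", values_to = "value")
}

#' @export
glance.fcm_trace <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$states),
    n_updates = nrow(x$raw),
    termination = x$termination,
    period = x$period,
    max_abs_final = max(abs(x$states[nrow(x$states), ]))
  )
}

#' Write a simulation trace to CSV plus a JSON sidecar
#'
#' One row per state vector, one column per concept, preceded by a `step`
#' column; termination metadata (status, period, settings) goes to
#' `<path>.json`.
#'
#' @param trace An `fcm_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fcm_trace"))
  df <- tibble::as_tibble(trace$states)
  df <- dplyr::mutate(df, step = seq_len(nrow(df)) - 1L, .before = 1)
  readr::write_csv(df, path)
  meta <- list(
    termination = trace$termination,
    period = trace$period,
    threshold = trace$settings$threshold,
    epsilon = trace$settings$epsilon,
    max_iter = trace$settings$max_iter,
    self_memory = trace$settings$self_memory,
    clamp = as.list(trace$settings$clamp)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
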