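#' Signed weighted concept map
#'
#' The core container: an ordered concept list plus an N-by-N real matrix
#' `W`, where `W[j, i]` is the weight of the directed influence of concept
#' `j` on concept `i` (zero where no edge). Entries lie in \eqn{[-1, 1]}.
#' A diagonal entry, when present in a source matrix, is stored as given but
#' never enters the state update: self-influence is controlled by the
#' `self_memory` simulation setting.
#'
#' @param W Numeric matrix, or a data frame edge list with columns `source`,
#'   `target`, `weight`.
#' @param concepts Character vector of concept names. Defaults to the
#'   dimnames of `W` or, for an edge list, the union of endpoints in order of
#'   first appearance.
#' @return An object of class `concept_map`: list with `concepts` and `W`.
#' @export
concept_map <- function(W, concepts = NULL) {
  if (is.data.frame(W)) {
    el <- tibble::as_tibble(W)
    stopifnot(all(c("source", "target", "weight") %in% names(el)))
    if (is.null(concepts)) {
      concepts <- unique(c(rbind(el$source, el$target)))
    }
    M <- matrix(0, length(concepts), length(concepts),
                dimnames = list(concepts, concepts))
    bad <- setdiff(c(el$source, el$target), concepts)
    if (length(bad) > 0) {
      stop("edge endpoint not in concept list: ", bad[1], call. = FALSE)
    }
    M[cbind(el$source, el$target)] <- el$weight
    W <- M
  } else {
    W <- as.matrix(W)
    if (is.null(concepts)) {
      concepts <- rownames(W) %||% paste0("C", seq_len(nrow(W)))
    }
  }
  stopifnot(nrow(W) == ncol(W), length(concepts) == nrow(W))
  if (any(abs(W) > 1 + 1e-12)) {
    stop("weights must lie in [-1, 1]", call. = FALSE)
  }
  dimnames(W) <- list(concepts, concepts)
  structure(list(concepts = as.character(concepts), W = W),
            class = "concept_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.concept_map <- function(x, ...) {
  nz <- sum(x$W[row(x$W) != col(x$W)] != 0)
  cat(sprintf("<concept_map> %d concepts, %d directed edges\n",
              length(x$concepts), nz))
  cat(" ", paste(utils::head(x$concepts, 6), collapse = ", "),
      if (length(x$concepts) > 6) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.concept_map <- function(x, ...) {
  idx <- which(x$W != 0 & row(x$W) != col(x$W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    source = x$concepts[idx[, 1]],
    target = x$concepts[idx[, 2]],
    weight = x$W[idx]
  )
}

#' @export
glance.concept_map <- function(x, ...) {
  e <- tidy(x)
  tibble::tibble(
    n_concepts = length(x$concepts),
    n_edges = nrow(e),
    n_negative = sum(e$weight < 0),
    min_abs_weight = if (nrow(e)) min(abs(e$weight)) else NA_real_,
    max_abs_weight = if (nrow(e)) max(abs(e$weight)) else NA_real_
  )
}

#' Read / write a weighted map as a delimited edge list
#'
#' The edge-list dialect has columns `source`, `target`, `weight`; weights
#' are written with six decimal places, and a read of a written file is exact
#' at that printed precision. Isolated concepts survive the round trip via
#' the optional `concepts` argument of the reader (the writer records the
#' full concept list in a `# concepts:` header comment which the reader
#' honours).
#'
#' @param map A `concept_map`.
#' @param path File path.
#' @param concepts Optional explicit concept ordering for the reader.
#' @return `read_concept_map()` returns a `concept_map`;
#'   `write_concept_map()` returns `path` invisibly.
#' @export
write_concept_map <- function(map, path) {
  stopifnot(inherits(map, "concept_map"))
  el <- tidy(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# concepts: ", paste(map$concepts, collapse = "|")), con)
  writeLines("source,target,weight", con)
  if (nrow(el) > 0) {
    writeLines(sprintf("%s,%s,%.6f", el$source, el$target, el$weight), con)
  }
  invisible(path)
}

#' @rdname write_concept_map
#' @export
read_concept_map <- function(path, concepts = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(concepts) && startsWith(first, "# concepts: ")) {
    concepts <- strsplit(sub("^# concepts: ", "", first), "|",
                         fixed = TRUE)[[1]]
  }
  el <- readr::read_csv(path, comment = "#",
                        col_types = readr::cols(
                          source = "c", target = "c", weight = "d"
                        ))
  concept_map(el, concepts)
}

#' Read a concept map from an adjacency-matrix CSV
#'
#' First column holds row concept names; remaining columns are the weights,
#' one column per concept in the same order. Diagonal entries are stored as
#' given (see [concept_map()]).
#'
#' @param path CSV path.
#' @return A `concept_map`.
#' @export
read_adjacency_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    concept = readr::col_character(), .default = readr::col_double()
  ))
  M <- as.matrix(df[, -1])
  rownames(M) <- df$concept
  stopifnot(identical(colnames(M), df$concept))
  concept_map(M, df$concept)
}
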