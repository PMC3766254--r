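#' Five-level ordinal scale for linguistic evidence
#'
#' Linguistic statements harvested from empirical studies are graded on a
#' five-level Likert-type scale: Very Low, Low, Medium, High, Very High.
#' The codes are totally ordered `VL < L < M < H < VH`.
#'
#' @format A character vector of the five level codes, in increasing order.
#' @export
fcm_levels <- c("VL", "L", "M", "H", "VH")

# canonical concept registry for the packaged homelessness map; the map's
# source tables use three naming variants (full names, abbreviations, and
# drifted labels), all funnelled to one canonical name per node
.hl_concepts <- tibble::tibble(
  index = 1:14,
  name = c(
    "Homelessness",
    "Criminal Justice System Involvement",
    "Poverty",
    "Unemployment",
    "Education",
    "Income",
    "Addiction",
    "Social Support Network",
    "Family Breakdown",
    "Mental Illness",
    "Non-Government Assistance",
    "Childhood Homelessness",
    "Government Assistance",
    "Cost of Housing"
  )
)

.hl_aliases <- c(
  "cjs" = "Criminal Justice System Involvement",
  "ngo" = "Non-Government Assistance",
  "social systems network" = "Social Support Network",
  "social network support" = "Social Support Network",
  "social network" = "Social Support Network",
  "childhood hardships" = "Childhood Homelessness",
  "addictions" = "Addiction"
)

#' Canonical concepts of the packaged homelessness map
#'
#' @return A tibble with columns `index` and `name` listing the 14 concepts,
#'   Homelessness first.
#' @export
homelessness_concepts <- function() {
  .hl_concepts
}

#' Normalize a concept label to its canonical name
#'
#' Maps the abbreviations and label variants used across the packaged
#' evidence tables (e.g. `"CJS"`, `"NGO"`, `"Social Systems Network"`,
#' `"Childhood hardships"`) to one canonical concept name each. Labels
#' already canonical (up to case and whitespace) pass through unchanged.
#'
#' @param x Character vector of concept labels.
#' @param concepts Character vector of canonical names to resolve against.
#' @return Character vector of canonical names; labels that match nothing are
#'   returned trimmed but otherwise untouched (validation happens downstream).
#' @export
normalize_concept <- function(x, concepts = homelessness_concepts()$name) {
  x <- gsub("\\s+", " ", trimws(x))
  key <- tolower(x)
  out <- x
  hit_alias <- key %in% names(.hl_aliases)
  out[hit_alias] <- unname(.hl_aliases[key[hit_alias]])
  idx <- match(tolower(out), tolower(concepts))
  out[!is.na(idx)] <- concepts[idx[!is.na(idx)]]
  out
}

#' Assemble a validated linguistic knowledge base
#'
#' A knowledge base couples an ordered concept list with a set of directed
#' influence edges. Each edge carries a sign (+1 facilitating, -1 inhibiting)
#' and exactly three ordinal linguistic levels, one per supporting study.
#'
#' @param edges A data frame with columns `source`, `target`, `sign`,
#'   `level1`, `level2`, `level3` and optionally `refs` (semicolon-separated
#'   citation tags). Source/target may be concept names or aliases.
#' @param concepts Character vector of concept names in display order, or a
#'   data frame with a `name` column. Defaults to the union of edge endpoints
#'   in order of first appearance.
#' @return An object of class `fcm_kb`: a list with tibbles `concepts`
#'   (columns `index`, `name`) and `edges`.
#' @examples
#' kb <- knowledge_base(tibble::tibble(
#'   source = "Poverty", target = "Addiction", sign = 1,
#'   level1 = "L", level2 = "L", level3 = "L"
#' ))
#' evidence_counts(kb)
#' @export
knowledge_base <- function(edges, concepts = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("source", "target", "sign", "level1", "level2", "level3")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("knowledge base rows must carry columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"refs" %in% names(edges)) edges$refs <- NA_character_

  if (is.null(concepts)) {
    concepts <- unique(c(rbind(edges$source, edges$target)))
  }
  if (is.data.frame(concepts)) concepts <- concepts$name
  concepts <- as.character(concepts)
  if (anyDuplicated(concepts)) {
    stop("duplicate concept names in concept list", call. = FALSE)
  }

  edges$source <- normalize_concept(edges$source, concepts)
  edges$target <- normalize_concept(edges$target, concepts)
  for (col in c("source", "target")) {
    bad <- which(!edges[[col]] %in% concepts)
    if (length(bad) > 0) {
      stop(sprintf("unknown concept name '%s' in row %d",
                   edges[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  if (any(edges$source == edges$target)) {
    bad <- which(edges$source == edges$target)[1]
    stop(sprintf("self-influence not allowed (row %d: '%s')", bad,
                 edges$source[bad]), call. = FALSE)
  }
  if (!all(edges$sign %in% c(-1, 1))) {
    bad <- which(!edges$sign %in% c(-1, 1))[1]
    stop(sprintf("sign must be +1 or -1 (row %d)", bad), call. = FALSE)
  }
  for (col in c("level1", "level2", "level3")) {
    bad <- which(!edges[[col]] %in% fcm_levels)
    if (length(bad) > 0) {
      stop(sprintf("expected 3 linguistic levels from {%s}; row %d has '%s'",
                   paste(fcm_levels, collapse = ", "), bad[1],
                   edges[[col]][bad[1]]), call. = FALSE)
    }
  }
  pair <- paste(edges$source, edges$target, sep = " -> ")
  if (anyDuplicated(pair)) {
    bad <- which(duplicated(pair))[1]
    stop(sprintf("duplicate edge '%s' (row %d)", pair[bad], bad),
         call. = FALSE)
  }

  structure(
    list(
      concepts = tibble::tibble(index = seq_along(concepts), name = concepts),
      edges = edges[, c(required, "refs")]
    ),
    class = "fcm_kb"
  )
}

#' @export
print.fcm_kb <- function(x, ...) {
  cat(sprintf("<fcm_kb> %d concepts, %d edges (%d linguistic terms)\n",
              nrow(x$concepts), nrow(x$edges), 3L * nrow(x$edges)))
  print(x$edges, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.fcm_kb <- function(x, ...) {
  x$edges
}

#' @importFrom generics glance
#' @export
glance.fcm_kb <- function(x, ...) {
  evidence_counts(x)
}

#' Read a knowledge base from a delimited file
#'
#' The file format is CSV with columns `source_id`, `source_name`,
#' `target_id`, `target_name`, `sign` (`+` or `-`), `level1`, `level2`,
#' `level3`, `refs`. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param concepts Optional concept list (character vector or data frame with
#'   columns `index`, `name`); defaults to the concepts declared by the
#'   id/name columns of the file itself, ordered by id.
#' @return An `fcm_kb` object.
#' @seealso [write_knowledge_base()], [homelessness_kb()]
#' @export
read_knowledge_base <- function(path, concepts = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (is.null(concepts)) {
    decl <- dplyr::bind_rows(
      tibble::tibble(index = as.integer(raw$source_id), name = raw$source_name),
      tibble::tibble(index = as.integer(raw$target_id), name = raw$target_name)
    )
    decl$name <- normalize_concept(decl$name, unique(decl$name))
    decl <- dplyr::distinct(dplyr::arrange(decl, .data$index))
    if (anyDuplicated(decl$index)) {
      stop("conflicting concept declarations in ", path, call. = FALSE)
    }
    concepts <- decl$name
  }
  sign_num <- dplyr::case_when(
    trimws(raw$sign) %in% c("+", "+1", "1") ~ 1,
    trimws(raw$sign) %in% c("-", "-1") ~ -1,
    TRUE ~ NA_real_
  )
  edges <- tibble::tibble(
    source = raw$source_name, target = raw$target_name, sign = sign_num,
    level1 = trimws(raw$level1), level2 = trimws(raw$level2),
    level3 = trimws(raw$level3),
    refs = if ("refs" %in% names(raw)) raw$refs else NA_character_
  )
  knowledge_base(edges, concepts)
}

#' Write a knowledge base to a delimited file
#'
#' Inverse of [read_knowledge_base()]: `read_knowledge_base(write_knowledge_base(kb, f))`
#' reproduces `kb` field-for-field.
#'
#' @param kb An `fcm_kb` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "fcm_kb"))
  idx <- stats::setNames(kb$concepts$index, kb$concepts$name)
  out <- tibble::tibble(
    source_id = idx[kb$edges$source],
    source_name = kb$edges$source,
    target_id = idx[kb$edges$target],
    target_name = kb$edges$target,
    sign = ifelse(kb$edges$sign > 0, "+", "-"),
    level1 = kb$edges$level1, level2 = kb$edges$level2,
    level3 = kb$edges$level3, refs = kb$edges$refs
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Summarize the evidence behind a knowledge base
#'
#' @param kb An `fcm_kb` object.
#' @return A one-row tibble with `n_edges`, `n_concepts`, and `n_terms`
#'   (always `3 * n_edges`: three linguistic statements per concept pair).
#' @examples
#' evidence_counts(homelessness_kb())
#' @export
evidence_counts <- function(kb) {
  stopifnot(inherits(kb, "fcm_kb"))
  tibble::tibble(
    n_edges = nrow(kb$edges),
    n_concepts = nrow(kb$concepts),
    n_terms = 3L * nrow(kb$edges)
  )
}

#' Build a term lexicon from phrase/level pairs
#'
#' The lexicon is a closed word bank mapping lower-cased phrases to ordinal
#' levels. Lookups are exact-phrase after case-folding and trimming; there is
#' no stemming. Some published word banks list a phrase under more than one
#' level; `multiple` controls how such duplicates are resolved.
#'
#' @param entries Data frame with columns `phrase` and `level`.
#' @param multiple One of `"first"` (keep the first listing, scanning levels
#'   in increasing order as printed), `"highest"` (keep the highest level), or
#'   `"error"`.
#' @return A named character vector of levels keyed by normalized phrase,
#'   classed `fcm_lexicon`.
#' @export
term_lexicon <- function(entries, multiple = c("first", "highest", "error")) {
  multiple <- match.arg(multiple)
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("phrase", "level") %in% names(entries)))
  if (!all(entries$level %in% fcm_levels)) {
    stop("lexicon levels must be one of ", paste(fcm_levels, collapse = ", "),
         call. = FALSE)
  }
  phrase <- tolower(gsub("\\s+", " ", trimws(entries$phrase)))
  level <- entries$level
  dup <- duplicated(phrase)
  if (any(dup)) {
    conflicting <- unique(phrase[dup][level[dup] !=
      level[match(phrase[dup], phrase)]])
    if (multiple == "error" && length(conflicting) > 0) {
      stop("phrase listed under more than one level: ",
           paste(conflicting, collapse = "; "), call. = FALSE)
    }
    if (multiple == "highest") {
      ord <- order(match(level, fcm_levels))  # ascending; later wins below
      phrase <- phrase[ord]; level <- level[ord]
      keep <- !duplicated(phrase, fromLast = TRUE)
    } else {
      keep <- !duplicated(phrase)
    }
    phrase <- phrase[keep]; level <- level[keep]
  }
  structure(stats::setNames(level, phrase), class = "fcm_lexicon")
}

#' Read a term lexicon from CSV
#'
#' @param path CSV with columns `phrase`, `level`.
#' @param multiple Duplicate policy, see [term_lexicon()].
#' @return An `fcm_lexicon` object.
#' @export
read_lexicon <- function(path, multiple = "first") {
  term_lexicon(
    readr::read_csv(path, col_types = readr::cols(.default = "c")),
    multiple = multiple
  )
}

#' Grade a linguistic phrase on the ordinal scale
#'
#' @param phrase Character vector of phrases (case and surrounding whitespace
#'   are ignored).
#' @param lexicon An `fcm_lexicon`; defaults to the packaged word bank.
#' @return Character vector of level codes (`"VL"` ... `"VH"`).
#' @examples
#' lookup_level("profound")     # "VH"
#' lookup_level("significant")  # "H"
#' @export
lookup_level <- function(phrase, lexicon = homelessness_lexicon()) {
  stopifnot(inherits(lexicon, "fcm_lexicon"))
  key <- tolower(gsub("\\s+", " ", trimws(phrase)))
  hit <- match(key, names(lexicon))
  if (anyNA(hit)) {
    stop("unclassified term: '", phrase[which(is.na(hit))[1]],
         "' (extend the lexicon to grade it)", call. = FALSE)
  }
  unname(lexicon[hit])
}
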