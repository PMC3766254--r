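#' Triangular fuzzy partition of the unit interval
#'
#' Builds the five-level partition used to translate ordinal linguistic
#' levels into fuzzy sets on the weight universe \eqn{[0, 1]}. The interior
#' levels L, M, H are symmetric triangles centred at 0.25, 0.5, 0.75 with
#' half-width 0.25; VL and VH are boundary shoulders peaking at 0 and 1:
#'
#' \preformatted{VL = (0, 0, 0.25)   L = (0, 0.25, 0.5)   M = (0.25, 0.5, 0.75)
#' H = (0.5, 0.75, 1)  VH = (0.75, 1, 1)}
#'
#' Every point of the universe has positive membership in at least one level,
#' and adjacent levels cross at membership 0.5.
#'
#' @param grid_points Number of uniformly spaced sample points on
#'   \eqn{[0, 1]} used for aggregation and centroid integration. At the
#'   default 1001 the discretization error of a defuzzified value is below
#'   1e-5; doubling the grid changes no value by more than 1e-3.
#' @return An object of class `fcm_partition`: list with `mfs` (named list of
#'   `(left, peak, right)` triples) and `grid`.
#' @export
fuzzy_partition <- function(grid_points = 1001) {
  stopifnot(is.numeric(grid_points), grid_points >= 101)
  structure(
    list(
      mfs = list(
        VL = c(left = 0, peak = 0, right = 0.25),
        L = c(left = 0, peak = 0.25, right = 0.5),
        M = c(left = 0.25, peak = 0.5, right = 0.75),
        H = c(left = 0.5, peak = 0.75, right = 1),
        VH = c(left = 0.75, peak = 1, right = 1)
      ),
      grid = seq(0, 1, length.out = as.integer(grid_points))
    ),
    class = "fcm_partition"
  )
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf("<fcm_partition> 5 triangular levels on [0,1], %d grid points\n",
              length(x$grid)))
  invisible(x)
}

#' Evaluate a triangular membership function
#'
#' Piecewise-linear hat: 0 outside `[left, right]`, 1 at `peak`, linear in
#' between. Degenerate sides (`left == peak` or `peak == right`) give the
#' boundary shoulders used for VL and VH.
#'
#' @param x Numeric vector of points in \eqn{[0, 1]}.
#' @param mf Either a `(left, peak, right)` numeric triple or a level code
#'   (`"VL"` ... `"VH"`) resolved against `partition`.
#' @param partition An `fcm_partition` (used only when `mf` is a level code).
#' @return Membership degrees in \eqn{[0, 1]}.
#' @examples
#' membership_degree(0.5, "M")    # 1
#' membership_degree(0.625, "M")  # 0.5
#' @export
membership_degree <- function(x, mf, partition = fuzzy_partition()) {
  if (is.character(mf)) {
    mf <- match.arg(mf, fcm_levels)
    mf <- partition$mfs[[mf]]
  }
  stopifnot(is.numeric(mf), length(mf) == 3)
  a <- mf[[1]]; b <- mf[[2]]; cc <- mf[[3]]
  stopifnot(a <= b, b <= cc)
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
  dn <- if (cc > b) (cc - x) / (cc - b) else as.numeric(x <= cc)
  pmax(0, pmin(up, dn, 1))
}

#' Aggregate fully fired rule consequents by pointwise maximum
#'
#' Each linguistic statement about an edge becomes one Mamdani rule whose
#' antecedent ("the source concept is ON") is binary and fires at full
#' strength, so min-implication leaves each consequent membership function
#' untouched. Aggregation is the pointwise maximum of the consequent sets,
#' sampled on the partition grid.
#'
#' @param levels Character vector of level codes (the packaged evidence
#'   carries exactly three per edge; any positive number is accepted).
#' @param partition An `fcm_partition`.
#' @return An object of class `fcm_aggregate`: list with `grid` and
#'   `membership` (values in \eqn{[0, 1]}, nonzero somewhere).
#' @export
aggregate_rules <- function(levels, partition = fuzzy_partition()) {
  stopifnot(length(levels) >= 1, all(levels %in% fcm_levels))
  membership <- Reduce(pmax, lapply(levels, function(lv) {
    membership_degree(partition$grid, lv, partition)
  }))
  structure(list(grid = partition$grid, membership = membership,
                 levels = levels),
            class = "fcm_aggregate")
}

#' Centroid defuzzification
#'
#' Centre of mass \eqn{\int x \mu(x) dx / \int \mu(x) dx} of an aggregated
#' membership curve, computed by the trapezoid rule on the sampling grid.
#'
#' @param agg An `fcm_aggregate` from [aggregate_rules()].
#' @return A crisp value in \eqn{(0, 1)}.
#' @examples
#' p <- fuzzy_partition()
#' defuzzify_centroid(aggregate_rules(c("L", "L", "L"), p))  # 0.25
#' defuzzify_centroid(aggregate_rules(c("M", "L", "H"), p))  # 0.5
#' @export
defuzzify_centroid <- function(agg) {
  stopifnot(inherits(agg, "fcm_aggregate"))
  mu <- agg$membership
  if (all(mu == 0)) {
    stop("cannot defuzzify an everywhere-zero aggregate", call. = FALSE)
  }
  g <- agg$grid
  h <- diff(g)
  w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid quadrature weights
  sum(g * mu * w) / sum(mu * w)
}

#' Crisp signed weight of one evidence edge
#'
#' The three ordinal levels are pushed through the fuzzy inference system
#' (full-strength rules, max aggregation, centroid defuzzification) to give a
#' magnitude in \eqn{(0, 1)}; the edge's sign (type of influence) is applied
#' afterwards, outside the fuzzy computation.
#'
#' @param levels Character vector of three level codes, or a one-row data
#'   frame / list with fields `sign`, `level1`, `level2`, `level3`.
#' @param sign `+1` or `-1`; ignored when `levels` carries its own sign.
#' @param partition An `fcm_partition`.
#' @return Signed weight in \eqn{[-1, 1]} with magnitude in \eqn{(0, 1)}.
#' @examples
#' edge_weight(c("M", "H", "VH"))            # ~ +0.667
#' edge_weight(c("M", "L", "H"), sign = -1)  # -0.5
#' @export
edge_weight <- function(levels, sign = 1, partition = fuzzy_partition()) {
  if (is.list(levels) || is.data.frame(levels)) {
    ev <- levels
    sign <- ev$sign
    levels <- c(ev$level1, ev$level2, ev$level3)
  }
  stopifnot(length(levels) == 3, sign %in% c(-1, 1))
  sign * defuzzify_centroid(aggregate_rules(levels, partition))
}

#' Assemble the full weighted concept map from a knowledge base
#'
#' Runs one fuzzy inference system per edge and places the resulting signed
#' weight at `W[source, target]`. Cells without an edge are 0; the diagonal
#' is 0 (self-memory is a simulation setting, not a stored weight).
#'
#' @param kb An `fcm_kb` object.
#' @param partition An `fcm_partition`.
#' @return A [concept_map()] whose weight matrix has one nonzero
#'   off-diagonal entry per edge.
#' @examples
#' fcm <- weight_matrix(homelessness_kb())
#' tidy(fcm)
#' @export
weight_matrix <- function(kb, partition = fuzzy_partition()) {
  stopifnot(inherits(kb, "fcm_kb"))
  n <- nrow(kb$concepts)
  W <- matrix(0, n, n, dimnames = list(kb$concepts$name, kb$concepts$name))
  if (nrow(kb$edges) > 0) {
    w <- purrr::pmap_dbl(
      kb$edges[, c("sign", "level1", "level2", "level3")],
      function(sign, level1, level2, level3) {
        edge_weight(c(level1, level2, level3), sign, partition)
      }
    )
    W[cbind(kb$edges$source, kb$edges$target)] <- w
  }
  concept_map(W, kb$concepts$name)
}
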