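# Independent oracles used to cross-check the package's computations.
# These deliberately share no code with the implementation paths they check.

# analytic membership of one linguistic level (same published geometry,
# evaluated directly, no grid)
oracle_mu <- function(x, level) {
  p <- switch(level,
    VL = c(0, 0, 0.25), L = c(0, 0.25, 0.5), M = c(0.25, 0.5, 0.75),
    H = c(0.5, 0.75, 1), VH = c(0.75, 1, 1)
  )
  sapply(x, function(xx) {
    if (xx < p[1] || xx > p[3]) return(0)
    up <- if (p[2] > p[1]) (xx - p[1]) / (p[2] - p[1]) else 1
    dn <- if (p[3] > p[2]) (p[3] - xx) / (p[3] - p[2]) else 1
    min(up, dn, 1)
  })
}

# centroid by adaptive quadrature on the analytic max-union
oracle_centroid <- function(levels) {
  mu <- function(x) do.call(pmax, lapply(levels, function(l) oracle_mu(x, l)))
  num <- stats::integrate(function(x) x * mu(x), 0, 1,
                          subdivisions = 2000, rel.tol = 1e-10)$value
  den <- stats::integrate(mu, 0, 1, subdivisions = 2000,
                          rel.tol = 1e-10)$value
  num / den
}

# all 35 unordered triples over the five levels
all_level_triples <- function() {
  lv <- c("VL", "L", "M", "H", "VH")
  out <- list()
  for (i in 1:5) for (j in i:5) for (k in j:5) {
    out[[length(out) + 1]] <- c(lv[i], lv[j], lv[k])
  }
  out
}

# mirror of a level set about the middle of the scale
mirror_levels <- function(levels) {
  c(VL = "VH", L = "H", M = "M", H = "L", VH = "VL")[levels]
}

# brute-force degree centrality: explicit double loop over ordered pairs
oracle_degree <- function(W) {
  n <- nrow(W)
  sapply(seq_len(n), function(x) {
    s <- 0
    for (y in seq_len(n)) {
      if (y == x) next
      s <- s + abs(W[x, y]) + abs(W[y, x])
    }
    s
  })
}

# all-pairs shortest paths by min-plus matrix powers on inverse weights
oracle_distances <- function(W, big_m = NULL) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W != 0] <- 1 / abs(W[W != 0])
  diag(D) <- 0
  for (rep in seq_len(n)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      through <- min(D[i, ] + D[, j])
      if (through < D[i, j]) D[i, j] <- through
    }
  }
  diag(D) <- 0
  if (!is.null(big_m)) D[is.infinite(D)] <- big_m
  D
}

# quantile by the standard linear-interpolation rule (type 7), by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# small positive two-layer chain map: every path to the sink has positive
# sign product by construction
positive_chain_map <- function(weights) {
  n <- length(weights) + 1
  W <- matrix(0, n, n)
  for (i in seq_along(weights)) W[i + 1, 1] <- weights[i]
  concept_map(W, c("Sink", paste0("X", seq_along(weights))))
}
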