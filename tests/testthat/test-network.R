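test_that("degree centrality matches the consistent published rows", {
  fcm <- homelessness_map()
  deg <- degree_centrality(fcm)
  d <- stats::setNames(deg$degree, deg$concept)
  expect_equal(unname(d["Childhood Homelessness"]), 1.2500, tolerance = 0.01)
  expect_equal(unname(d["Non-Government Assistance"]), 0.5000,
               tolerance = 0.005)
  expect_equal(unname(d["Income"]), 1.3978, tolerance = 0.02)
  expect_equal(unname(d["Government Assistance"]), 1.3844, tolerance = 0.02)
  expect_equal(unname(d["Cost of Housing"]), 0.4984, tolerance = 0.02)
  # isolated node has zero degree
  iso <- concept_map(matrix(0, 3, 3), c("A", "B", "C"))
  expect_equal(degree_centrality(iso)$degree, rep(0, 3))
})

test_that("degree is sign-invariant and equals the brute-force double loop", {
  for (seed in 1:10) {
    m <- random_map(4 + seed %% 7, density = 0.35, negative_fraction = 0.4,
                    sink_concept = FALSE, seed = seed)
    deg <- degree_centrality(m)$degree
    expect_equal(deg, oracle_degree(m$W), tolerance = 1e-12)
    flipped <- m
    flipped$W <- -m$W
    expect_equal(degree_centrality(flipped)$degree, deg)
  }
})

test_that("inverse-weight distances behave as published on the map", {
  fcm <- homelessness_map()
  el <- tidy(fcm)
  # greatest single-edge distance is 4, from the weight-0.25 edge
  expect_equal(max(1 / abs(el$weight)), 4, tolerance = 1e-6)
  D <- concept_distances(fcm)
  # Cost of Housing reaches only Homelessness; the other 12 pairs sit at Big-M
  coh <- D["Cost of Housing", ]
  expect_equal(sum(coh == 100), 12)
  expect_lt(coh["Homelessness"], 100)
  # triangle inequality holds after Big-M substitution is applied last
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) {
    expect_lte(D[i, j], min(D[i, ] + D[, j]) + 1e-9)
  }
})

test_that("distances and closeness equal independent oracles on random maps", {
  st <- centrality_settings()
  for (seed in 1:50) {
    n <- 3 + seed %% 8
    m <- random_map(n, density = 0.3, negative_fraction = 0.5,
                    sink_concept = seed %% 2 == 0, seed = 100 + seed)
    D <- concept_distances(m, st)
    expect_equal(unname(D), oracle_distances(m$W, big_m = st$big_m),
                 tolerance = 1e-9, info = paste("seed", seed))
    cl <- closeness_centrality(m, st)
    expect_equal(cl$closeness_raw, 1 / rowSums(oracle_distances(m$W, 100)),
                 tolerance = 1e-9)
    expect_equal(degree_centrality(m, st)$degree, oracle_degree(m$W),
                 tolerance = 1e-12)
  }
})

test_that("strengthening an edge never lengthens any finite distance", {
  for (seed in 1:8) {
    m <- random_map(7, density = 0.3, sink_concept = FALSE, seed = seed)
    D1 <- concept_distances(m)
    el <- tidy(m)
    pick <- el[1 + seed %% nrow(el), ]
    m$W[pick$source, pick$target] <- sign(pick$weight) *
      min(1, abs(pick$weight) * 1.5)
    D2 <- concept_distances(m)
    finite <- D1 < 100
    expect_true(all(D2[finite] <= D1[finite] + 1e-9))
  }
})

test_that("closeness of the housing-cost sink matches the hand computation", {
  fcm <- homelessness_map()
  w <- tidy(fcm)
  w_coh <- abs(w$weight[w$source == "Cost of Housing"])
  cl <- closeness_centrality(fcm)
  raw <- cl$closeness_raw[cl$concept == "Cost of Housing"]
  expect_equal(raw, 1 / (12 * 100 + 1 / w_coh), tolerance = 1e-12)
  # ~8.32 at the 10^4 display scale
  expect_equal(cl$closeness_scaled[cl$concept == "Cost of Housing"],
               8.3194, tolerance = 0.02)
})

test_that("raising Big-M preserves the closeness ranking of the map", {
  fcm <- homelessness_map()
  r100 <- closeness_centrality(fcm, centrality_settings(big_m = 100))
  r1000 <- closeness_centrality(fcm, centrality_settings(big_m = 1000))
  expect_equal(order(-r100$closeness_raw), order(-r1000$closeness_raw))
})

test_that("single-concept maps are flagged degenerate", {
  solo <- concept_map(matrix(0, 1, 1), "A")
  expect_warning(cl <- closeness_centrality(solo), "degenerate")
  expect_true(is.infinite(cl$closeness_raw))
})

test_that("sensitivity sweeps expose each concept's leverage", {
  fcm <- homelessness_map()
  sw <- sensitivity_sweep(fcm, "Addiction")
  expect_equal(nrow(sw), 10)
  expect_equal(sw$initial, seq(0.1, 1, by = 0.1))
  # addiction's influence is monotone increasing
  expect_true(all(diff(sw$outcome_value) > 0))
  expect_error(sensitivity_sweep(fcm, "Homelessness"), "outcome concept")
  expect_error(sensitivity_sweep(fcm, "No Such Thing"), "unknown concept")
})

test_that("a concept with no path to the outcome sweeps flat", {
  # B -> C only; A (outcome) is untouched by B
  W <- matrix(0, 3, 3)
  W[2, 3] <- 0.6
  m <- concept_map(W, c("A", "B", "C"))
  sw <- sensitivity_sweep(m, "B", outcome = "A")
  expect_equal(diff(range(sw$outcome_value)), 0)
  expect_equal(sweep_summary(sw)$iqr, 0)
})

test_that("a single-edge toy map matches the closed form", {
  # X -> outcome with weight 0.5; after one update h = tanh(0.5 v)
  W <- matrix(0, 2, 2)
  W[2, 1] <- 0.5
  m <- concept_map(W, c("Homelessness", "X"))
  sw <- sensitivity_sweep(m, "X", iterations = 1)
  expect_equal(sw$outcome_value, tanh(0.5 * seq(0.1, 1, by = 0.1)),
               tolerance = 1e-12)
})

test_that("sweep summaries reproduce reference quartiles and the box contrast", {
  x <- c(0.12, 0.5, 0.31, 0.9, 0.77, 0.05, 0.66, 0.42, 0.58, 0.23)
  sw <- tibble::tibble(concept = "toy", initial = seq(0.1, 1, 0.1),
                       outcome_value = x)
  class(sw) <- c("fcm_sweep", class(sw))
  s <- sweep_summary(sw)
  expect_equal(s$q1, oracle_quantile(x, 0.25))
  expect_equal(s$median, oracle_quantile(x, 0.5))
  expect_equal(s$q3, oracle_quantile(x, 0.75))
  expect_equal(s$min, min(x))
  expect_equal(s$max, max(x))
  # a strong direct influence saturates: narrower box than a weak one
  fcm <- homelessness_map()
  boxes <- sweep_summary(list(
    sensitivity_sweep(fcm, "Addiction"),
    sensitivity_sweep(fcm, "Cost of Housing")
  ))
  expect_lt(boxes$iqr[boxes$concept == "Addiction"],
            boxes$iqr[boxes$concept == "Cost of Housing"])
})
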