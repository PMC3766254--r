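test_that("triangular membership evaluates the hat shape", {
  expect_equal(membership_degree(0.5, "M"), 1)
  expect_equal(membership_degree(0.25, "M"), 0)
  expect_equal(membership_degree(0.625, "M"), 0.5)
  # boundary shoulders peak at the ends of the universe
  expect_equal(membership_degree(0, "VL"), 1)
  expect_equal(membership_degree(1, "VH"), 1)
  expect_equal(membership_degree(0.125, "VL"), 0.5)
  # partition covers the whole universe
  p <- fuzzy_partition()
  cover <- Reduce(pmax, lapply(fcm_levels, function(l) {
    membership_degree(p$grid, l, p)
  }))
  expect_true(all(cover > 0))
})

test_that("aggregation is an order-free pointwise maximum", {
  p <- fuzzy_partition()
  # idempotent: repeating one level gives that level's set
  agg <- aggregate_rules(c("M", "M", "M"), p)
  expect_equal(agg$membership, membership_degree(p$grid, "M", p))
  # permutation invariance
  a1 <- aggregate_rules(c("L", "H", "M"), p)
  a2 <- aggregate_rules(c("M", "L", "H"), p)
  expect_identical(a1$membership, a2$membership)
  # {L, L, H}: union of the two hats, symmetric about 0.5
  u <- aggregate_rules(c("L", "L", "H"), p)$membership
  expect_equal(u, rev(u))
  # {M, H, VH}: support is [0.25, 1]
  s <- aggregate_rules(c("M", "H", "VH"), p)$membership
  expect_true(all(s[p$grid < 0.25] == 0))
  expect_true(all(s[p$grid > 0.26] > 0))
})

test_that("centroid defuzzification reproduces the worked values", {
  p <- fuzzy_partition()
  d <- function(lv) defuzzify_centroid(aggregate_rules(lv, p))
  expect_equal(d(c("L", "L", "L")), 0.25, tolerance = 1e-6)
  expect_equal(d(c("M", "L", "H")), 0.5, tolerance = 1e-6)
  # boundary-shoulder case: within the 0.02 absolute calibration band
  expect_lt(abs(d(c("M", "H", "VH")) - 0.648), 0.02)
  zero <- aggregate_rules("M", p)
  zero$membership[] <- 0
  expect_error(defuzzify_centroid(zero), "zero aggregate")
})

test_that("grid centroid agrees with adaptive quadrature on all 35 triples", {
  p <- fuzzy_partition()
  for (tr in all_level_triples()) {
    expect_lt(abs(defuzzify_centroid(aggregate_rules(tr, p)) -
                    oracle_centroid(tr)), 1e-5,
              label = paste(tr, collapse = "/"))
  }
})

test_that("mirror symmetry holds over the whole triple lattice", {
  p <- fuzzy_partition()
  d <- function(lv) defuzzify_centroid(aggregate_rules(lv, p))
  for (tr in all_level_triples()) {
    # mirrored level sets defuzzify to mirrored values (the partition is
    # symmetric under x -> 1 - x)
    expect_equal(d(mirror_levels(tr)), 1 - d(tr), tolerance = 1e-9,
                 info = paste(tr, collapse = "/"))
  }
})

test_that("interior-level raises are monotone; boundary shoulders are not", {
  p <- fuzzy_partition()
  d <- function(lv) defuzzify_centroid(aggregate_rules(lv, p))
  # raising a level within {L, M, H} never decreases the magnitude
  interior <- c("L", "M", "H")
  for (i in 1:3) for (j in i:3) for (k in j:3) {
    tr <- interior[c(i, j, k)]
    for (pos in 1:3) {
      rank <- match(tr[pos], interior)
      if (rank == 3) next
      up <- tr
      up[pos] <- interior[rank + 1]
      expect_gte(d(up) + 1e-9, d(tr),
                 label = sprintf("%s raised to %s", paste(tr, collapse = ""),
                                 paste(up, collapse = "")))
    }
  }
  # known property of max-union centroids: a raise that folds a unique hat
  # into an adjacent boundary shoulder can remove interior mass and lower
  # the centroid. Pin the canonical counterexample so a change in the
  # aggregation scheme would be noticed.
  expect_lt(d(c("M", "VH", "VH")), d(c("M", "H", "VH")))
  expect_equal(d(c("M", "VH", "VH")), oracle_centroid(c("M", "VH", "VH")),
               tolerance = 1e-5)
})

test_that("defuzzified values are stable under grid refinement", {
  for (tr in list(c("M", "H", "VH"), c("VL", "L", "M"), c("H", "VL", "M"))) {
    v1 <- defuzzify_centroid(aggregate_rules(tr, fuzzy_partition(1001)))
    v2 <- defuzzify_centroid(aggregate_rules(tr, fuzzy_partition(2001)))
    expect_lt(abs(v1 - v2), 1e-3)
  }
})

test_that("edge weights carry the influence sign outside the FIS", {
  expect_equal(edge_weight(c("M", "L", "H"), sign = -1), -0.5,
               tolerance = 1e-6)
  expect_lt(abs(edge_weight(c("M", "H", "VH"), sign = 1) - 0.648), 0.02)
  expect_equal(edge_weight(c("L", "L", "L"), sign = 1), 0.25,
               tolerance = 1e-6)
  # row-wise interface
  row <- tibble::tibble(sign = -1, level1 = "M", level2 = "L", level3 = "H")
  expect_equal(edge_weight(row), -0.5, tolerance = 1e-6)
})

test_that("weight matrix equals per-edge FIS calls, zero elsewhere", {
  kb <- random_evidence(6, seed = 11)
  p <- fuzzy_partition()
  fcm <- weight_matrix(kb, p)
  expect_equal(sum(fcm$W != 0), 6)
  for (i in seq_len(nrow(kb$edges))) {
    e <- kb$edges[i, ]
    expect_equal(fcm$W[e$source, e$target], edge_weight(e, partition = p))
  }
  # empty knowledge base gives an all-zero matrix over its concepts
  kb0 <- knowledge_base(kb$edges[0, ], concepts = c("A", "B", "C"))
  expect_equal(weight_matrix(kb0)$W, matrix(0, 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
})

test_that("packaged map weights live in (0,1) with minimum 0.25", {
  fcm <- homelessness_map()
  w <- tidy(fcm)$weight
  expect_equal(length(w), 31)
  expect_true(all(abs(w) > 0 & abs(w) < 1))
  expect_equal(min(abs(w)), 0.25, tolerance = 1e-6)
  # that minimum is the poverty -> addiction influence
  el <- tidy(fcm)
  expect_equal(el$source[which.min(abs(el$weight))], "Poverty")
  expect_equal(el$target[which.min(abs(el$weight))], "Addiction")
})

test_that("weighted map round-trips through the edge-list dialect", {
  fcm <- homelessness_map()
  path <- withr::local_tempfile(fileext = ".csv")
  write_concept_map(fcm, path)
  back <- read_concept_map(path)
  expect_equal(back$concepts, fcm$concepts)
  expect_equal(back$W, fcm$W, tolerance = 5e-7)  # printed at 6 decimals
  expect_identical(readLines(path), {
    write_concept_map(fcm, path2 <- withr::local_tempfile(fileext = ".csv"))
    readLines(path2)
  })
})
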