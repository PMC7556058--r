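test_that("SUM aggregation is pointwise addition of member functions", {
  bank <- mf_bank()
  # single term reproduces its own membership function
  single <- mf_aggregate("medium", bank)
  expect_equal(max(single$mu), 1)
  expect_equal(single$mu[single$x == 0.5], 1)
  expect_equal(single$mu[single$x == 0.25], 0)

  # repeated terms scale linearly
  twice <- mf_aggregate(c("low", "low"), bank)
  expect_equal(twice$mu, 2 * mf_aggregate("low", bank)$mu, tolerance = 1e-12)

  # multiplicity shows at the peak
  trio <- mf_aggregate(c("high", "very_high", "very_high"), bank)
  expect_equal(trio$mu[trio$x == 0.9],
               2 + oracle_triangle(0.9, 0.45, 0.7, 0.95), tolerance = 1e-12)

  # order of opinions is irrelevant
  a <- mf_aggregate(c("low", "high", "very_low"), bank)
  b <- mf_aggregate(c("very_low", "low", "high"), bank)
  expect_identical(a$mu, b$mu)

  expect_error(mf_aggregate(character(0), bank), "at least one")
  expect_error(mf_aggregate("enormous", bank), "unknown")
})

test_that("centroid returns the peak of interior symmetric functions and is scale-free", {
  bank <- mf_bank()
  for (lv in c("low", "medium", "high")) {
    cv <- mf_aggregate(lv, bank)
    expect_equal(mf_centroid(cv), bank$peak[bank$level == lv],
                 tolerance = 1e-9)
  }
  # truncation at the axis ends shifts the outer centroids inward
  expect_equal(mf_centroid(mf_aggregate("very_low", bank)), 0.1329268,
               tolerance = 1e-6)
  expect_equal(mf_centroid(mf_aggregate("very_high", bank)), 0.8670732,
               tolerance = 1e-6)

  cv <- mf_aggregate(c("medium", "high"), bank)
  scaled <- list(x = cv$x, mu = 7.3 * cv$mu)
  expect_equal(mf_centroid(scaled), mf_centroid(cv), tolerance = 1e-12)

  expect_error(mf_centroid(list(x = c(0, 1), mu = c(0, 0))), "zero")
})

test_that("module centroid matches the fine-grid quadrature oracle", {
  bank <- mf_bank()
  levels <- bank$level
  # the worked three-opinion example
  expect_equal(
    mf_centroid(mf_aggregate(c("high", "very_high", "very_high"), bank)),
    oracle_centroid(c("high", "very_high", "very_high")),
    tolerance = 1e-6
  )
  set.seed(2024)
  for (rep in seq_len(100)) {
    terms <- sample(levels, sample(1:5, 1), replace = TRUE)
    expect_equal(mf_centroid(mf_aggregate(terms, bank)),
                 oracle_centroid(terms), tolerance = 1e-6)
  }
})

test_that("expert opinions become a signed matrix with voted signs and pooled magnitudes", {
  ids <- c("A", "B", "C")
  empty <- weights_from_opinions(
    data.frame(source = character(0), target = character(0),
               sign = numeric(0), term = character(0), expert = character(0)),
    ids)
  expect_identical(empty, matrix(0, 3, 3, dimnames = list(ids, ids)))

  ops <- data.frame(
    source = "A", target = "B", sign = 1,
    term = c("high", "very_high", "very_high"), expert = c("e1", "e2", "e3"),
    stringsAsFactors = FALSE
  )
  W <- weights_from_opinions(ops, ids)
  expect_equal(W["A", "B"], oracle_centroid(c("high", "very_high", "very_high")),
               tolerance = 1e-6)
  expect_true(all(W[W != 0] >= -1 & W[W != 0] <= 1))

  # minority sign does not shrink the pooled magnitude, only loses the vote
  ops_mixed <- ops
  ops_mixed$sign <- c(1, 1, -1)
  ops_mixed$term <- c("high", "high", "high")
  W2 <- weights_from_opinions(ops_mixed, ids)
  expect_gt(W2["A", "B"], 0)
  expect_equal(abs(W2["A", "B"]),
               mf_centroid(mf_aggregate(c("high", "high", "high"))),
               tolerance = 1e-9)

  # tied vote is a consensus failure
  ops_tie <- ops_mixed[1:2, ]
  ops_tie$sign <- c(1, -1)
  expect_error(weights_from_opinions(ops_tie, ids), "tied sign")

  # one expert may not judge the same pair twice
  ops_dup <- ops
  ops_dup$expert <- c("e1", "e1", "e3")
  expect_error(weights_from_opinions(ops_dup, ids), "duplicate")

  expect_error(weights_from_opinions(
    data.frame(source = "A", target = "A", sign = 1, term = "low",
               expert = "e1"), ids), "self-referential")
  expect_error(weights_from_opinions(
    data.frame(source = "A", target = "Z", sign = 1, term = "low",
               expert = "e1"), ids), "unknown concept")
})

test_that("magnitudes from any opinion set stay in [0,1]", {
  set.seed(5)
  ids <- c("A", "B")
  levels <- mf_bank()$level
  for (rep in seq_len(25)) {
    k <- sample(1:6, 1)
    ops <- data.frame(source = "A", target = "B", sign = 1,
                      term = sample(levels, k, replace = TRUE),
                      expert = paste0("e", seq_len(k)),
                      stringsAsFactors = FALSE)
    w <- weights_from_opinions(ops, ids)["A", "B"]
    expect_true(w >= 0 && w <= 1)
  }
})
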