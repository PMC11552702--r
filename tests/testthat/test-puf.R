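test_that("level ratings rescale to severities with fixed anchors", {
  s <- rescale_level_ratings(rep(72.9, 7), rep(43.9, 7))
  expect_equal(unname(s[, "l1"]), rep(0, 7))
  expect_equal(unname(s[, "l4"]), rep(1, 7))
  expect_equal(s["IN", "l2"], 0.271, tolerance = 1e-12)
  expect_equal(rescale_level_ratings(rep(100, 7), rep(0, 7))["AC", "l2"], 0)
  expect_equal(rescale_level_ratings(rep(0, 7), rep(0, 7))["AC", "l2"], 1)
  expect_error(rescale_level_ratings(rep(101, 7), rep(0, 7)), "\\[0, 100\\]")
})

test_that("swing weights normalise to sum one", {
  expect_equal(unname(normalize_weights(rep(100, 7))), rep(1 / 7, 7))
  expect_equal(unname(normalize_weights(c(100, 0, 0, 0, 0, 0, 0))),
               c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(normalize_weights(c(100, 50, 50, 0, 0, 0, 0))),
               c(0.5, 0.25, 0.25, 0, 0, 0, 0))
  expect_error(normalize_weights(rep(0, 7)), "zero")
  expect_error(normalize_weights(c(120, rep(10, 6))), "\\[0, 100\\]")
})

test_that("anchoring transformation follows both branches, is continuous at 0 and caps at -1", {
  expect_equal(compute_anchor("worst", 50), 0.5)
  expect_equal(compute_anchor("worst", 0), 0)
  expect_equal(compute_anchor("dead", 0), 0)
  expect_equal(compute_anchor("dead", 20), -0.25)
  expect_identical(compute_anchor("dead", 50), -1)
  expect_identical(compute_anchor("dead", 80), -1)
  expect_identical(compute_anchor("dead", 100), -1)   # limiting case
  # cap engages strictly above the midpoint
  expect_gt(compute_anchor("dead", 49.99), -1)
  expect_gt(compute_anchor("dead", 50.01, cap = FALSE), -Inf)
  expect_lt(compute_anchor("dead", 50.01, cap = FALSE), -1)
  expect_error(compute_anchor("worst", 101), "\\[0, 100\\]")
  expect_error(compute_anchor("sideways", 10), "worst")
})

test_that("uniform respondent yields the closed-form PUF", {
  puf <- build_puf(make_record())
  expect_equal(unname(puf$decrements[, "l4"]), rep(0.1, 7), tolerance = 1e-12)
  expect_equal(puf$anchor, 0.3)
  expect_equal(puf_utility(puf, "1111111"), 1)
  expect_equal(puf_utility(puf, "4111111"), 0.9, tolerance = 1e-12)
  expect_equal(puf_utility(puf, "4444444"), 0.3, tolerance = 1e-12)

  flat <- build_puf(make_record(anchor_vas = 100))
  expect_equal(unname(flat$decrements), matrix(0, 7, 4))
  expect_equal(puf_utility(flat, c("1111111", "4444444", "2413121")),
               rep(1, 3))
})

test_that("matrix evaluation agrees with a brute-force per-state oracle", {
  states <- enumerate_states()
  for (seed in c(3, 17)) {
    rec <- random_record(seed)
    puf <- build_puf(rec)
    expect_equal(puf_utility(puf, states), brute_force_utilities(rec, states),
                 tolerance = 1e-12)
  }
})

test_that("PUF invariants hold over random respondents", {
  for (seed in 1:25) {
    rec <- random_record(seed)
    puf <- build_puf(rec)
    expect_equal(sum(puf$weights), 1, tolerance = 1e-9)
    expect_gte(puf$anchor, -1)
    expect_lte(puf$anchor, 1)
    expect_equal(unname(puf$decrements[, 1]), rep(0, 7))
    expect_equal(sum(puf$decrements[, 4]), 1 - puf$anchor, tolerance = 1e-9)
    expect_equal(puf_utility(puf, "1111111"), 1, tolerance = 1e-9)
    expect_equal(puf_utility(puf, "4444444"), puf$anchor, tolerance = 1e-9)
  }
})

test_that("utility is monotone under level-wise domination for monotone ratings", {
  for (seed in 1:10) {
    puf <- build_puf(random_record(seed, monotone = TRUE))
    set.seed(seed + 1000)
    for (i in 1:20) {
      a <- sample.int(4, 7, replace = TRUE)
      b <- pmin(a + sample(0:2, 7, replace = TRUE), 4)   # b dominates a
      expect_gte(puf_utility(puf, format_state_index(a)),
                 puf_utility(puf, format_state_index(b)) - 1e-12)
    }
  }
})

test_that("QC flags fire on the defined inconsistencies and nowhere else", {
  expect_length(validate_respondent(make_record()), 0L)
  nm <- make_record(vas_l2 = c(20, rep(70, 6)), vas_l3 = c(80, rep(30, 6)))
  expect_identical(validate_respondent(nm), "NONMONOTONE_LEVELS")
  expect_true("ALL_ZERO_WEIGHTS" %in%
                validate_respondent(make_record(weights = rep(0, 7))))
  bad <- validate_respondent(make_record(anchor_vas = 150))
  expect_true(all(c("RANGE_VIOLATION", "INVERTED_GLOBAL") %in% bad))
  expect_identical(validate_respondent(make_record(anchor_vas = -5)),
                   "RANGE_VIOLATION")
  expect_true("RANGE_VIOLATION" %in%
                validate_respondent(make_record(state = "1111119")))
})
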