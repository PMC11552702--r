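test_that("default profiles carry the published summary statistics", {
  p <- default_profiles()
  expect_equal(p$GP$weights["PD", "mean"], 88.3)
  expect_equal(p$GP$weights["PD", "sd"], 20.3)
  expect_equal(p$GP$level_ratings["IN", "l2_mean"], 72.9)
  expect_equal(p$GP$level_ratings["AC", "l3_mean"], 29.6)
  expect_equal(p$MI$level_ratings["IN", "l2_mean"], 61.9)
  expect_equal(p$GP$anchoring$p_worst, 0.66)
  expect_equal(p$MI$anchoring$p_worst, 0.72)
  # own-state distributions are calibrated to the reported mean severities
  expect_equal(sum(p$GP$own_state %*% (1:4)), 9.3, tolerance = 0.1)
  expect_equal(sum(p$MI$own_state %*% (1:4)), 16.7, tolerance = 0.1)
})

test_that("simulation is deterministic and structurally valid", {
  p <- default_profiles()$GP
  a <- simulate_respondents(p, 50, seed = 123)
  b <- simulate_respondents(p, 50, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, simulate_respondents(p, 50, seed = 124)))

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_respondents(a, f1)
  write_respondents(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_equal(nrow(simulate_respondents(p, 1, seed = 1)), 1L)
  expect_error(simulate_respondents(p, 0, seed = 1), ">= 1")

  flags <- validate_respondents(simulate_respondents(p, 300, seed = 7))
  expect_false(any(vapply(flags, function(f)
    any(f %in% c("RANGE_VIOLATION", "ALL_ZERO_WEIGHTS", "INVERTED_GLOBAL")),
    logical(1))))
})

test_that("simulated samples recover the profile's calibrated moments", {
  p <- default_profiles()$GP
  recs <- simulate_respondents(p, 2000, seed = 99)
  # level-rating mean (target feasible, matched exactly by calibration)
  se <- sd(recs$vas_IN_l2) / sqrt(nrow(recs))
  expect_lt(abs(mean(recs$vas_IN_l2) - 72.9), 2 * se + 0.05)
  # anchoring branch probability
  share <- mean(recs$anchor_branch == "worst")
  expect_lt(abs(share - 0.66), 2 * sqrt(0.66 * 0.34 / 2000))
  # yardstick pinning: every respondent has max weight exactly 100
  w <- as.matrix(recs[, sprintf("weight_%s", DIMS)])
  expect_true(all(apply(w, 1, max) == 100))
  # dimension rank order stabilises to the profile's mean order
  dw <- dimension_weighting(recs)
  expect_equal(dw$rank[dw$dimension == "PD"], 1L)
  expect_equal(dw$rank[dw$dimension == "AC"], 2L)
})

test_that("about 6% of pre-cap anchors fall below -1 at n = 500", {
  for (nm in c("GP", "MI")) {
    recs <- simulate_respondents(default_profiles()[[nm]], 500, seed = 55)
    s <- anchoring_summary(recs)
    expect_gt(s$pct_below_minus1, 3)
    expect_lt(s$pct_below_minus1, 9)
  }
})

test_that("expected decrements reduce to the deterministic PUF for a degenerate profile", {
  p <- default_profiles()$GP
  p$level_ratings[, c("l2_sd", "l3_sd")] <- 0
  p$weights[, "sd"] <- 0
  p$anchoring <- list(p_worst = 1, worst_mean = 30, worst_sd = 0,
                      dead_mean = 28, dead_sd = 0)
  ed <- expected_decrements(p, n_mc = 100, seed = 1)
  rec <- simulate_respondents(p, 1, seed = 2)
  puf <- build_puf(rec)
  expect_equal(unname(ed), unname(puf$decrements), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a symmetric profile yields symmetric expected decrements", {
  p <- default_profiles()$GP
  p$level_ratings[] <- rep(c(60, 20, 30, 20), each = 7)
  p$weights[] <- rep(c(80, 25), each = 7)
  ed <- expected_decrements(p, n_mc = 40000, seed = 3)
  se <- attr(ed, "mc_se")
  for (l in 2:4) {
    spread <- max(ed[, l]) - min(ed[, l])
    expect_lt(spread, 6 * max(se[, l]))
  }
})

test_that("profiles round-trip through JSON", {
  p <- default_profiles()$MI
  path <- tempfile(fileext = ".json")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$level_ratings, p$level_ratings)
  expect_equal(back$weights, p$weights)
  expect_equal(back$own_state, p$own_state)
  expect_equal(back$anchoring, p$anchoring)
  expect_identical(back$name, "MI")
  # a profile read from file drives the generator identically
  expect_identical(simulate_respondents(back, 20, seed = 6),
                   simulate_respondents(p, 20, seed = 6))
})
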