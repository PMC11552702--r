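test_that("level-rating summary reports raw VAS moments with fixed anchors", {
  recs <- rbind(make_record(id = "a", vas_l2 = rep(40, 7)),
                make_record(id = "b", vas_l2 = rep(80, 7)))
  s <- level_rating_summary(recs)
  l2 <- s[s$level == 2, ]
  expect_equal(l2$mean, rep(60, 7))
  expect_equal(l2$sd, rep(sqrt(800), 7), tolerance = 1e-9)   # 28.28
  expect_equal(s[s$level == 1, "mean"], rep(100, 7))
  expect_equal(s[s$level == 4, "mean"], rep(0, 7))

  same <- rbind(make_record(id = "a", vas_l2 = rep(60, 7)),
                make_record(id = "b", vas_l2 = rep(60, 7)))
  s2 <- level_rating_summary(same)
  expect_equal(s2[s2$level == 2, "sd"], rep(0, 7))
  expect_error(level_rating_summary(make_record()[0, ]), "empty")
})

test_that("dimension ranks follow descending mean weight with canonical tie-break", {
  w <- rep(50, 7)
  w[3] <- 100   # PD
  recs <- rbind(make_record(id = "a", weights = w),
                make_record(id = "b", weights = w))
  dw <- dimension_weighting(recs)
  expect_equal(dw$rank[dw$dimension == "PD"], 1L)
  # remaining six dimensions tie at 50: ranks follow canonical order
  expect_equal(dw$rank, c(2L, 3L, 1L, 4L, 5L, 6L, 7L))
})

test_that("coefficient differences vanish on identical samples", {
  pufs <- lapply(1:10, function(s) build_puf(random_record(s)))
  cd <- coefficient_differences(pufs, pufs, iterations = 200, seed = 1)
  expect_equal(nrow(cd), 21L)
  expect_equal(cd$difference, rep(0, 21))
  expect_false(any(cd$significant))

  one <- coefficient_differences(pufs[1], pufs[2], iterations = 50, seed = 1)
  gap <- build_puf(random_record(1))$decrements -
    build_puf(random_record(2))$decrements
  expect_equal(one$difference, as.vector(gap[, 2:4]), tolerance = 1e-12)
  expect_equal(one$ci_low, one$difference, tolerance = 1e-12)  # degenerate
})

test_that("a planted decrement gap is estimated and flagged significant", {
  profiles <- default_profiles()
  pa <- profiles$GP
  pb <- pa
  pb$level_ratings["IN", "l2_mean"] <- pa$level_ratings["IN", "l2_mean"] - 20
  ea <- expected_decrements(pa, n_mc = 50000, seed = 11)
  eb <- expected_decrements(pb, n_mc = 50000, seed = 12)
  delta <- ea["IN", "l2"] - eb["IN", "l2"]
  expect_lt(delta, 0)    # lower VAS mean = higher severity = larger decrement

  ra <- simulate_respondents(pa, 400, seed = 21)
  rb <- simulate_respondents(pb, 400, seed = 22)
  cd <- coefficient_differences(build_pufs(ra), build_pufs(rb),
                                iterations = 1000, seed = 5)
  row <- cd[cd$dimension == "IN" & cd$level == 2, ]
  se <- (row$ci_high - row$ci_low) / (2 * 1.96)   # bootstrap SE of the gap
  expect_lt(abs(row$difference - delta), 3 * se)
  expect_true(row$significant)
})

test_that("anchoring summary counts branches and applies the cap rule", {
  recs <- rbind(make_record(id = "a", anchor_branch = "worst",
                            anchor_vas = 100),
                make_record(id = "b", anchor_branch = "worst",
                            anchor_vas = 100))
  s <- anchoring_summary(recs)
  expect_equal(s$pct_worst_preferred, 100)
  expect_equal(s$mean_anchor, 1)
  expect_equal(s$n_below_minus1, 0L)

  mix <- rbind(make_record(id = "a", anchor_branch = "worst", anchor_vas = 50),
               make_record(id = "b", anchor_branch = "dead", anchor_vas = 80))
  s2 <- anchoring_summary(mix)
  expect_equal(s2$n_below_minus1, 1L)          # raw anchor -4
  expect_equal(s2$mean_anchor, (0.5 + -1) / 2) # capped value enters the mean
  expect_equal(s2$pct_worst_preferred, 50)
})

test_that("utility-difference distribution matches its closed-form oracle", {
  gp <- published_value_set("GP")
  mi <- published_value_set("MI")
  same <- utility_difference_distribution(gp, gp)
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)

  d <- utility_difference_distribution(gp, mi)
  # under uniform enumeration each level appears with probability 1/4, so
  # the mean difference is minus the sum over dimensions of the
  # mean-over-levels decrement gap
  gap <- gp$decrements - mi$decrements
  expect_equal(d$mean, -sum(rowMeans(gap)), tolerance = 1e-12)
  # and dimensions are independent, so the variances add
  expect_equal(d$sd, sqrt(sum(apply(gap, 1, function(g)
    mean(g^2) - mean(g)^2))), tolerance = 1e-12)
})

test_that("extreme-state table is consistent with the full tabulations", {
  gp <- published_value_set("GP")
  mi <- published_value_set("MI")
  k1 <- extreme_state_table(gp, mi, k = 1)
  expect_identical(k1$state, c("1111111", "4444444"))

  ext <- extreme_state_table(gp, mi, k = 25)
  expect_equal(nrow(ext), 50L)
  ta <- tabulate_all_states(gp)
  tb <- tabulate_all_states(mi)
  expect_equal(ext$rank_a, match(ext$state, ta$state))
  expect_equal(ext$rank_b, match(ext$state, tb$state))
  expect_equal(ext$rank_difference, ext$rank_b - ext$rank_a)
  expect_equal(attr(ext, "bottom_mean_difference"),
               mean(ext$difference[ext$tail == "bottom"]))
})

test_that("comparison plots build without error", {
  gp <- published_value_set("GP")
  mi <- published_value_set("MI")
  expect_s3_class(plot_utility_histogram(gp, mi), "ggplot")
  expect_s3_class(plot_utility_curves(gp, mi), "ggplot")
})

test_that("compare_samples bundles all five analyses", {
  ra <- simulate_respondents(default_profiles()$GP, 40, seed = 31)
  rb <- simulate_respondents(default_profiles()$MI, 40, seed = 32)
  rep <- compare_samples(ra, rb, iterations = 200, seed = 9, k = 5)
  expect_s3_class(rep, "mobqol_comparison")
  expect_equal(nrow(rep$coefficient_differences), 21L)
  expect_equal(sort(rep$dimension_weighting$a$rank), 1:7)
  expect_equal(nrow(rep$extreme_states), 10L)
  expect_true(is.numeric(rep$utility_difference$mean))
})
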