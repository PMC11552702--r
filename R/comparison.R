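# Between-sample comparisons: level-rating and swing-weight summaries,
# bootstrap inference on coefficient differences, anchoring summaries, the
# per-state utility-difference distribution, and extreme-state tables.

#' Level-rating summary for a sample
#'
#' Mean and sample SD of the raw VAS positions (0--100 scale) for levels 2
#' and 3 of each dimension. Levels 1 and 4 are the fixed scale anchors 100
#' and 0 and are reported as such.
#'
#' @param records Data.frame of respondent records.
#' @return Data.frame with columns `dimension`, `level`, `mean`, `sd`
#'   (28 rows: 7 dimensions x 4 levels).
#' @export
level_rating_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty sample", call. = FALSE)
  rows <- lapply(dim_codes(), function(d) {
    l2 <- records[[sprintf("vas_%s_l2", d)]]
    l3 <- records[[sprintf("vas_%s_l3", d)]]
    data.frame(
      dimension = d, level = 1:4,
      mean = c(100, mean(l2), mean(l3), 0),
      sd = c(0, stats::sd(l2), stats::sd(l3), 0),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dimension weighting and ranking for a sample
#'
#' Mean and sample SD of the raw swing weights per dimension, with ranks
#' assigned by descending mean weight (rank 1 = most important). Exact ties
#' in the mean are broken by canonical dimension order (AC first).
#'
#' @param records Data.frame of respondent records.
#' @return Data.frame with columns `dimension`, `mean`, `sd`, `rank`.
#' @export
dimension_weighting <- function(records) {
  if (nrow(records) == 0L) stop("empty sample", call. = FALSE)
  w <- sapply(dim_codes(), function(d) {
    x <- records[[sprintf("weight_%s", d)]]
    c(mean(x), stats::sd(x))
  })
  out <- data.frame(dimension = dim_codes(), mean = w[1, ], sd = w[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- rank(-out$mean, ties.method = "first")
  out
}

#' Bootstrap comparison of mean model coefficients between two samples
#'
#' For each of the 21 non-zero dimension-level coefficients, the difference
#' in mean anchored decrements (sample A minus sample B) with a percentile
#' bootstrap 95% CI: each sample is resampled independently with
#' replacement, preserving its size, `iterations` times. A difference is
#' flagged significant (5% level) when its CI excludes 0.
#'
#' @param pufs_a,pufs_b Lists of `mobqol_puf` objects.
#' @param iterations Bootstrap iterations (default 10,000).
#' @param seed Integer seed.
#' @return Data.frame with columns `dimension`, `level`, `difference`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
coefficient_differences <- function(pufs_a, pufs_b, iterations = 10000L,
                                    seed = 1L) {
  if (length(pufs_a) < 1L || length(pufs_b) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  Da <- t(vapply(pufs_a, function(p) as.vector(p$decrements),
                 numeric(n_dims * n_levels)))
  Db <- t(vapply(pufs_b, function(p) as.vector(p$decrements),
                 numeric(n_dims * n_levels)))
  diff_mean <- colMeans(Da) - colMeans(Db)
  boot <- with_seed(seed, {
    na <- nrow(Da); nb <- nrow(Db)
    ca <- stats::rmultinom(iterations, na, rep(1 / na, na))
    cb <- stats::rmultinom(iterations, nb, rep(1 / nb, nb))
    crossprod(ca, Da) / na - crossprod(cb, Db) / nb
  })
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  keep <- as.vector(outer(seq_len(n_dims), 2:4,
                          function(d, l) d + (l - 1L) * n_dims))
  out <- data.frame(
    dimension = rep(dim_codes(), times = 3),
    level = rep(2:4, each = n_dims),
    difference = diff_mean[keep],
    ci_low = qs[1, keep], ci_high = qs[2, keep],
    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  out
}

#' Anchoring summary for a sample
#'
#' Counts and shares of respondents preferring the worst state 4444444 over
#' being dead, the mean and SD of the capped anchors, and the count and
#' share of pre-cap anchors below -1 (dead-preferred VAS above the midpoint).
#'
#' @param records Data.frame of respondent records.
#' @return A one-row data.frame with columns `n`, `n_worst_preferred`,
#'   `pct_worst_preferred`, `mean_anchor`, `sd_anchor`, `n_below_minus1`,
#'   `pct_below_minus1`.
#' @export
anchoring_summary <- function(records) {
  if (nrow(records) == 0L) stop("empty sample", call. = FALSE)
  branch <- records$anchor_branch
  vas <- records$anchor_vas
  capped <- compute_anchor(branch, vas)
  raw <- compute_anchor(branch, vas, cap = FALSE)
  n <- nrow(records)
  data.frame(
    n = n,
    n_worst_preferred = sum(branch == "worst"),
    pct_worst_preferred = 100 * mean(branch == "worst"),
    mean_anchor = mean(capped),
    sd_anchor = stats::sd(capped),
    n_below_minus1 = sum(raw < -1),
    pct_below_minus1 = 100 * mean(raw < -1))
}

#' Distribution of per-state utility differences between two value sets
#'
#' Scores every one of the 16,384 states under both value sets and
#' summarises the differences (A minus B) by exhaustive enumeration: mean,
#' population SD (divide by N), and quartiles by linear interpolation.
#'
#' @param vs_a,vs_b `mobqol_value_set` objects.
#' @return A list with elements `mean`, `sd`, `quartiles` (named 25%/50%/75%)
#'   and `differences` (the full vector, in lexicographic state order).
#' @examples
#' d <- utility_difference_distribution(published_value_set("GP"),
#'                                      published_value_set("MI"))
#' c(d$mean, d$sd)
#' @export
utility_difference_distribution <- function(vs_a, vs_b) {
  states <- enumerate_states()
  diffs <- state_utility(vs_a, states) - state_utility(vs_b, states)
  n <- length(diffs)
  list(mean = mean(diffs),
       sd = sqrt(sum((diffs - mean(diffs))^2) / n),
       quartiles = stats::quantile(diffs, c(0.25, 0.5, 0.75), type = 7),
       differences = diffs)
}

#' Top and bottom ranked states under two value sets
#'
#' The k best and k worst states by the first value set's ranking, with both
#' utilities, the utility difference (A minus B), both ranks, and the rank
#' difference (B rank minus A rank: positive means B ranks the state less
#' severely, i.e. closer to the top).
#'
#' @param vs_a,vs_b `mobqol_value_set` objects; ordering follows `vs_a`.
#' @param k States per tail (default 25).
#' @return Data.frame with columns `state`, `utility_a`, `utility_b`,
#'   `difference`, `rank_a`, `rank_b`, `rank_difference` and a `tail` column
#'   (`"top"`/`"bottom"`); attribute `bottom_mean_difference` holds the mean
#'   A-minus-B difference over the bottom k states.
#' @export
extreme_state_table <- function(vs_a, vs_b, k = 25L) {
  if (k < 1L || k > 4^n_dims / 2) stop("'k' out of range", call. = FALSE)
  ta <- tabulate_all_states(vs_a)
  tb <- tabulate_all_states(vs_b)
  rank_b <- stats::setNames(tb$rank, tb$state)
  u_b <- stats::setNames(tb$utility, tb$state)
  pick <- rbind(
    cbind(ta[seq_len(k), ], tail = "top"),
    cbind(ta[seq(nrow(ta) - k + 1L, nrow(ta)), ], tail = "bottom"))
  out <- data.frame(
    state = pick$state,
    utility_a = pick$utility,
    utility_b = unname(u_b[pick$state]),
    rank_a = pick$rank,
    rank_b = unname(rank_b[pick$state]),
    tail = pick$tail,
    stringsAsFactors = FALSE, row.names = NULL)
  out$difference <- out$utility_a - out$utility_b
  out$rank_difference <- out$rank_b - out$rank_a
  out <- out[, c("state", "utility_a", "utility_b", "difference",
                 "rank_a", "rank_b", "rank_difference", "tail")]
  attr(out, "bottom_mean_difference") <-
    mean(out$difference[out$tail == "bottom"])
  out
}

#' Full between-sample comparison report
#'
#' Bundles the five comparison analyses for two respondent samples: level
#' ratings, dimension weighting/ranking, coefficient differences with
#' bootstrap CIs, anchoring summaries, and (from the aggregated value sets)
#' the utility-difference distribution and extreme-state table.
#'
#' @param records_a,records_b Respondent data.frames for the two samples.
#' @param iterations Bootstrap iterations (default 10,000).
#' @param seed Integer seed.
#' @param k Extreme states per tail (default 25).
#' @return A list of class `mobqol_comparison`.
#' @export
compare_samples <- function(records_a, records_b, iterations = 10000L,
                            seed = 1L, k = 25L) {
  pufs_a <- build_pufs(records_a)
  pufs_b <- build_pufs(records_b)
  vs_a <- aggregate_value_set(pufs_a, iterations, seed, name = "A")
  vs_b <- aggregate_value_set(pufs_b, iterations, seed + 1L, name = "B")
  ud <- utility_difference_distribution(vs_a, vs_b)
  ud$differences <- NULL
  structure(list(
    level_rating_summary = list(a = level_rating_summary(records_a),
                                b = level_rating_summary(records_b)),
    dimension_weighting = list(a = dimension_weighting(records_a),
                               b = dimension_weighting(records_b)),
    coefficient_differences = coefficient_differences(pufs_a, pufs_b,
                                                      iterations, seed),
    anchoring_summary = list(a = anchoring_summary(records_a),
                             b = anchoring_summary(records_b)),
    utility_difference = ud,
    extreme_states = extreme_state_table(vs_a, vs_b, k),
    value_sets = list(a = vs_a, b = vs_b)
  ), class = "mobqol_comparison")
}

#' @export
print.mobqol_comparison <- function(x, ...) {
  cat("MobQoL-7D between-sample comparison\n")
  cat(sprintf("  mean (SD) per-state utility difference (A - B): %.3f (%.3f)\n",
              x$utility_difference$mean, x$utility_difference$sd))
  sig <- x$coefficient_differences[x$coefficient_differences$significant, ]
  cat(sprintf("  coefficients significantly different at 5%%: %d of 21\n",
              nrow(sig)))
  if (nrow(sig))
    cat(sprintf("    %s level %d: %+0.3f (%.3f; %.3f)\n", sig$dimension,
                sig$level, sig$difference, sig$ci_low, sig$ci_high), sep = "")
  invisible(x)
}

#' Histogram of utility values across all states, by value set
#'
#' Scores all 16,384 states under each value set and overlays frequency
#' histograms of the utilities on the 0--1 scale.
#'
#' @param vs_a,vs_b `mobqol_value_set` objects.
#' @param binwidth Histogram bin width (default 0.02).
#' @return A ggplot object.
#' @export
plot_utility_histogram <- function(vs_a, vs_b, binwidth = 0.02) {
  states <- enumerate_states()
  df <- data.frame(
    utility = c(state_utility(vs_a, states), state_utility(vs_b, states)),
    sample = rep(c(vs_a$name, vs_b$name), each = length(states)))
  ggplot2::ggplot(df, ggplot2::aes(x = utility, fill = sample)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "Utility value", y = "Number of health states",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Sorted utility curves across the state space, by value set
#'
#' Plots the utility of every state under both value sets, with states
#' ordered along the x-axis by the first set's ranking from worst to best
#' (so the first set traces a smooth curve and the second shows the
#' re-ranking scatter).
#'
#' @param vs_a,vs_b `mobqol_value_set` objects; ordering follows `vs_a`.
#' @return A ggplot object.
#' @export
plot_utility_curves <- function(vs_a, vs_b) {
  ta <- tabulate_all_states(vs_a)
  pos <- rev(seq_len(nrow(ta)))   # worst state first on the x-axis
  df <- data.frame(
    position = c(pos, pos),
    utility = c(ta$utility, state_utility(vs_b, ta$state)),
    sample = rep(c(vs_a$name, vs_b$name), each = nrow(ta)))
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = utility,
                                   colour = sample)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.5) +
    ggplot2::labs(x = sprintf("Health states ordered by %s ranking (worst to best)",
                              vs_a$name),
                  y = "Utility value", colour = NULL) +
    ggplot2::theme_minimal()
}
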