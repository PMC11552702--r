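# Group value sets: mean anchored decrements over respondents, with
# percentile-bootstrap confidence intervals, plus scoring and ranking of the
# full 16,384-state space.

new_value_set <- function(name, n, decrements, ci_low, ci_high, provenance) {
  dimnames(decrements) <- list(dim_codes(), paste0("l", 1:4))
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(decrements)
  vs <- structure(
    list(name = name, n_respondents = n, decrements = decrements,
         ci_low = ci_low, ci_high = ci_high, provenance = provenance),
    class = "mobqol_value_set"
  )
  validate_value_set(vs)
  vs
}

validate_value_set <- function(vs) {
  d <- vs$decrements
  if (!all(dim(d) == c(n_dims, n_levels)))
    stop("value set decrements must be a 7 x 4 matrix", call. = FALSE)
  if (any(abs(d[, 1]) > 1e-12))
    stop("level-1 decrements must be zero", call. = FALSE)
  if (any(vs$ci_low > d + 1e-9) || any(vs$ci_high < d - 1e-9))
    stop("confidence bounds must bracket the mean decrements", call. = FALSE)
  invisible(vs)
}

#' Aggregate personal utility functions into a value set
#'
#' The group value set is the arithmetic mean of the respondents' anchored
#' decrement matrices (respondent-level anchoring and capping happen before
#' aggregation). 95% confidence intervals are percentile bootstrap over
#' respondents: resample with replacement `iterations` times and take the
#' 2.5th / 97.5th percentiles of the resampled mean for each of the 21
#' non-zero coefficients.
#'
#' @param pufs List of `mobqol_puf` objects (at least one).
#' @param iterations Bootstrap iterations (default 10,000).
#' @param seed Integer seed making the bootstrap reproducible.
#' @param name Label for the value set (e.g. `"GP"`, `"MI"`).
#' @return A `mobqol_value_set`.
#' @examples
#' recs <- simulate_respondents(default_profiles()$GP, n = 20, seed = 7)
#' vs <- aggregate_value_set(build_pufs(recs), iterations = 200, seed = 1,
#'                           name = "demo")
#' state_utility(vs, "4444444")
#' @export
aggregate_value_set <- function(pufs, iterations = 10000L, seed = 1L,
                                name = "custom") {
  if (length(pufs) < 1L) stop("need at least one PUF", call. = FALSE)
  if (iterations < 1L) stop("'iterations' must be >= 1", call. = FALSE)
  stopifnot(all(vapply(pufs, inherits, logical(1), "mobqol_puf")))
  D <- t(vapply(pufs, function(p) as.vector(p$decrements),
                numeric(n_dims * n_levels)))        # n x 28
  mean_dec <- matrix(colMeans(D), n_dims, n_levels)
  n <- length(pufs)
  boot <- with_seed(seed, {
    counts <- stats::rmultinom(iterations, n, rep(1 / n, n))   # n x iter
    crossprod(counts, D) / n                                   # iter x 28
  })
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  ci_low <- matrix(qs[1, ], n_dims, n_levels)
  ci_high <- matrix(qs[2, ], n_dims, n_levels)
  # level-1 coefficients are structural zeros
  ci_low[, 1] <- ci_high[, 1] <- 0
  new_value_set(name, n, mean_dec, ci_low, ci_high,
                provenance = list(source = "aggregate_value_set",
                                  n = n, iterations = as.integer(iterations),
                                  seed = as.integer(seed)))
}

#' Utility of health states under a value set
#'
#' `u(state) = 1 - sum_d decrement[d, level_d]`; "1111111" always scores 1.
#'
#' @param vs A `mobqol_value_set`.
#' @param state Character vector of 7-digit state indices.
#' @return Numeric vector of utilities.
#' @examples
#' state_utility(published_value_set("GP"), c("1112111", "4444444"))
#' @export
state_utility <- function(vs, state) {
  stopifnot(inherits(vs, "mobqol_value_set"))
  decrement_utility(vs$decrements, state)
}

#' Score and rank the full state space
#'
#' Scores all 16,384 MobQoL-7D states under a value set and ranks them from
#' best (rank 1, always "1111111") to worst (rank 16,384). Ties are broken
#' by ascending lexicographic state index so the table is reproducible.
#'
#' @param vs A `mobqol_value_set`.
#' @return Data.frame with columns `state`, `utility`, `rank`, ordered by
#'   rank.
#' @export
tabulate_all_states <- function(vs) {
  states <- enumerate_states()
  u <- state_utility(vs, states)
  ord <- order(-u, states)
  data.frame(state = states[ord], utility = u[ord], rank = seq_along(states),
             stringsAsFactors = FALSE)
}

#' @export
print.mobqol_value_set <- function(x, ...) {
  cat(sprintf("MobQoL-7D value set '%s' (n = %d respondents)\n",
              x$name, x$n_respondents))
  cat("mean utility decrements (95% CI) by dimension and level:\n")
  fmt <- function(d, lo, hi) sprintf("%.3f (%.3f; %.3f)", d, lo, hi)
  out <- matrix("0", n_dims, n_levels - 1L,
                dimnames = list(dim_codes(), paste0("l", 2:4)))
  for (l in 2:4)
    out[, l - 1L] <- fmt(x$decrements[, l], x$ci_low[, l], x$ci_high[, l])
  print(out, quote = FALSE)
  cat(sprintf("utility range: %.3f (4444444) to 1.000 (1111111)\n",
              1 - sum(x$decrements[, 4])))
  invisible(x)
}

#' Round a value set for publication-style display
#'
#' Value sets are stored at full precision; this returns a copy with all
#' coefficients and bounds rounded to `digits` decimals (3 matches the
#' published tables).
#'
#' @param vs A `mobqol_value_set`.
#' @param digits Decimal places (default 3).
#' @return A `mobqol_value_set` with rounded matrices.
#' @export
round_value_set <- function(vs, digits = 3L) {
  vs$decrements <- round(vs$decrements, digits)
  vs$ci_low <- round(vs$ci_low, digits)
  vs$ci_high <- round(vs$ci_high, digits)
  vs
}

#' Write a value set to JSON
#'
#' Serialises name, sample size, per-level decrements, CI bounds and
#' provenance with stable key order; [read_value_set()] round-trips without
#' loss.
#'
#' @param vs A `mobqol_value_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "mobqol_value_set"))
  obj <- list(
    name = vs$name,
    n_respondents = vs$n_respondents,
    dimensions = dim_codes(),
    decrements = lapply(seq_len(n_dims), function(d) unname(vs$decrements[d, ])),
    ci_low = lapply(seq_len(n_dims), function(d) unname(vs$ci_low[d, ])),
    ci_high = lapply(seq_len(n_dims), function(d) unname(vs$ci_high[d, ])),
    provenance = vs$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a value set from JSON
#'
#' @param path File written by [write_value_set()].
#' @return A `mobqol_value_set`.
#' @export
read_value_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "double"
    m
  }
  new_value_set(obj$name, as.integer(obj$n_respondents),
                as_mat(obj$decrements), as_mat(obj$ci_low),
                as_mat(obj$ci_high), as.list(obj$provenance))
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
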