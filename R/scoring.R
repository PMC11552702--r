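# Applying a value set to state data: utilities, QALYs, population norms.

#' Score health states under a value set
#'
#' Element-wise [state_utility()] with row-identified parse errors, for use
#' on CSV-sourced state columns.
#'
#' @param states Character vector of 7-digit state indices.
#' @param vs A `mobqol_value_set`.
#' @return Numeric vector of utilities, same length as `states`.
#' @examples
#' score_states(c("1111111", "4444444"), published_value_set("GP"))
#' @export
score_states <- function(states, vs) {
  if (length(states) == 0L) return(numeric(0))
  for (i in seq_along(states)) {
    res <- try(parse_state_index(states[i]), silent = TRUE)
    if (inherits(res, "try-error"))
      stop(sprintf("row %d: %s", i,
                   conditionMessage(attr(res, "condition"))), call. = FALSE)
  }
  state_utility(vs, states)
}

#' Quality-adjusted life years from a utility trajectory
#'
#' A trajectory is a sequence of piecewise-constant segments; QALYs are the
#' sum of utility x duration over segments (no discounting).
#'
#' @param utility Numeric vector of segment utilities (each <= 1).
#' @param duration_years Numeric vector of non-negative segment durations in
#'   years.
#' @return Total QALYs (a single number).
#' @examples
#' compute_qalys(c(0.129, 1.0), c(1, 0.5))
#' @export
compute_qalys <- function(utility, duration_years) {
  if (length(utility) != length(duration_years))
    stop("'utility' and 'duration_years' lengths differ", call. = FALSE)
  if (anyNA(duration_years) || any(duration_years < 0))
    stop("durations must be non-negative", call. = FALSE)
  if (anyNA(utility) || any(utility > 1))
    stop("utilities must be <= 1", call. = FALSE)
  sum(utility * duration_years)
}

#' Population norms by gender and age band
#'
#' Groups scored utilities by gender x age band and reports the group mean
#' with a 95% t-distribution confidence interval and group size. Rows with
#' `"NotStated"` gender or age band are excluded. Groups smaller than
#' `min_group_size` are kept but flagged `small_sample`.
#'
#' @param scored Data.frame with columns `gender`, `age_band`, `utility`.
#' @param min_group_size Groups below this n are flagged (default 5).
#' @return Data.frame with columns `gender`, `age_band`, `mean_utility`,
#'   `ci_low`, `ci_high`, `n`, `small_sample`.
#' @export
population_norms <- function(scored, min_group_size = 5L) {
  stopifnot(all(c("gender", "age_band", "utility") %in% names(scored)))
  keep <- scored$gender != "NotStated" & scored$age_band != "NotStated" &
    !is.na(scored$gender) & !is.na(scored$age_band)
  scored <- scored[keep, , drop = FALSE]
  if (nrow(scored) == 0L)
    stop("no rows with stated gender and age band", call. = FALSE)
  groups <- split(scored$utility,
                  list(gender = scored$gender, age_band = scored$age_band),
                  drop = TRUE, sep = "\r")
  rows <- lapply(names(groups), function(key) {
    u <- groups[[key]]
    n <- length(u)
    m <- mean(u)
    half <- if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(u) / sqrt(n) else 0
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    data.frame(gender = parts[1], age_band = parts[2], mean_utility = m,
               ci_low = m - half, ci_high = m + half, n = n,
               small_sample = n < min_group_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gender, out$age_band), , drop = FALSE]
}
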