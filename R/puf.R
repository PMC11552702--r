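# Personal utility function (PUF) construction.
#
# A respondent's survey answers yield an additive utility model over the
# MobQoL-7D state space:
#   u(state) = 1 - sum_d  w_d * s_d(level_d) * (1 - anchor)
# where w are the normalised swing weights (sum 1), s_d the within-dimension
# level severities rescaled to [0,1] (level 1 = 0, level 4 = 1), and the
# anchor is the respondent's utility for the worst state 4444444 on the
# dead = 0 / full health = 1 scale, capped at -1.

#' Rescale VAS level ratings to severities
#'
#' Level-rating responses place levels 2 and 3 of each dimension on a
#' 0--100 VAS whose anchors are the worst (0) and best (100) level of that
#' dimension. Severities invert and rescale this to 0 (best level) -- 1
#' (worst level): level 1 is 0, level 4 is 1, and level k in {2, 3} is
#' `1 - vas_k / 100`.
#'
#' @param vas_l2,vas_l3 Numeric vectors of length 7 (canonical dimension
#'   order) with VAS positions in \[0, 100\].
#' @return A 7 x 4 numeric matrix of severities in \[0, 1\], rows named by
#'   dimension code, columns `l1`..`l4`.
#' @examples
#' rescale_level_ratings(rep(72.9, 7), rep(43.9, 7))["IN", ]
#' @export
rescale_level_ratings <- function(vas_l2, vas_l3) {
  check_vas(c(vas_l2, vas_l3), "level rating VAS")
  if (length(vas_l2) != n_dims || length(vas_l3) != n_dims)
    stop("need one level-2 and one level-3 rating per dimension", call. = FALSE)
  m <- cbind(l1 = 0, l2 = 1 - vas_l2 / 100, l3 = 1 - vas_l3 / 100, l4 = 1)
  rownames(m) <- dim_codes()
  m
}

#' Normalise swing weights
#'
#' Raw swing weights (0--100, with the respondent's most impactful dimension
#' pinned at 100 as the yardstick) are normalised to sum to 1.
#'
#' @param raw Numeric vector of 7 raw weights in \[0, 100\].
#' @return Numeric vector of 7 weights summing to 1, named by dimension code.
#' @examples
#' normalize_weights(c(100, 50, 50, 0, 0, 0, 0))
#' @export
normalize_weights <- function(raw) {
  if (length(raw) != n_dims)
    stop("need exactly 7 raw weights", call. = FALSE)
  if (anyNA(raw) || any(raw < 0) || any(raw > 100))
    stop("raw swing weights must lie in [0, 100]", call. = FALSE)
  s <- sum(raw)
  if (s <= 0)
    stop("all swing weights are zero: respondent preferences are undefined",
         call. = FALSE)
  stats::setNames(raw / s, dim_codes())
}

#' Anchor utility of the worst state from the dead-anchoring task
#'
#' Respondents first choose between the worst MobQoL-7D state 4444444 and
#' being dead, then place the less-preferred concept on a VAS.
#'
#' * `worst` branch (worst state preferred over dead): the worst state is
#'   placed at position p on a VAS from dead (0) to no mobility problems
#'   (100), so the anchor is `p / 100` in \[0, 1\].
#' * `dead` branch (dead preferred): dead is placed at position q on a VAS
#'   from the worst state (0) to no mobility problems (100). Requiring
#'   u(dead) = 0 and u(full health) = 1 on a scale where the worst state
#'   sits at 0 gives the projective rescaling `anchor = -q / (100 - q)`,
#'   which falls below -1 whenever q > 50 and is capped at -1 (q = 100 is
#'   the limiting case, capped).
#'
#' @param branch Character vector, each element `"worst"` or `"dead"`.
#' @param vas_position Numeric vector of VAS positions in \[0, 100\].
#' @param cap If `TRUE` (default) cap anchors below -1 at -1; if `FALSE`
#'   return the raw (pre-cap) value, which may be less than -1 (and `-Inf`
#'   for the q = 100 limiting case).
#' @return Numeric vector of anchors; with `cap = TRUE` always in \[-1, 1\].
#' @examples
#' compute_anchor(c("worst", "dead", "dead"), c(50, 20, 80))
#' @export
compute_anchor <- function(branch, vas_position, cap = TRUE) {
  if (length(branch) != length(vas_position))
    stop("'branch' and 'vas_position' lengths differ", call. = FALSE)
  if (!all(branch %in% c("worst", "dead")))
    stop("anchoring branch must be 'worst' or 'dead'", call. = FALSE)
  check_vas(vas_position, "anchoring VAS")
  a <- ifelse(branch == "worst",
              vas_position / 100,
              -vas_position / (100 - vas_position))
  if (cap) a <- pmax(a, -1)
  a
}

check_vas <- function(x, what) {
  if (anyNA(x) || any(x < 0) || any(x > 100))
    stop(sprintf("%s positions must lie in [0, 100]", what), call. = FALSE)
  invisible(x)
}

# pull the 7-vector of a column family (e.g. "vas_AC_l2"...) from a record
record_cols <- function(record, template) {
  nm <- sprintf(template, dim_codes())
  missing <- setdiff(nm, names(record))
  if (length(missing))
    stop("record is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.numeric(record[nm])
}

#' Build a personal utility function from one respondent record
#'
#' Combines the respondent's level ratings, swing weights and anchoring
#' response into an anchored additive utility model. The decrement for
#' dimension d at level l is `w_d * s_d(l) * (1 - anchor)`; level-1
#' decrements are zero, and the level-4 decrements sum to `1 - anchor`, so
#' the PUF assigns utility 1 to "1111111" and the anchor to "4444444".
#'
#' @param record A one-row data.frame or named list with the respondent CSV
#'   schema columns (see [read_respondents()]): `vas_<DIM>_l2`,
#'   `vas_<DIM>_l3`, `weight_<DIM>` for each of the 7 dimension codes,
#'   `anchor_branch` and `anchor_vas`.
#' @return An object of class `mobqol_puf`: a list with elements `anchor`,
#'   `weights` (length 7, sums to 1), `severities` (7 x 4), `decrements`
#'   (7 x 4) and `id`.
#' @examples
#' rec <- c(list(id = "r1", anchor_branch = "worst", anchor_vas = 30),
#'          as.list(setNames(rep(200 / 3, 7), sprintf("vas_%s_l2", c("AC",
#'            "CO", "PD", "IN", "SE", "ME", "AX")))),
#'          as.list(setNames(rep(100 / 3, 7), sprintf("vas_%s_l3", c("AC",
#'            "CO", "PD", "IN", "SE", "ME", "AX")))),
#'          as.list(setNames(rep(100, 7), sprintf("weight_%s", c("AC", "CO",
#'            "PD", "IN", "SE", "ME", "AX")))))
#' puf <- build_puf(rec)
#' puf_utility(puf, c("1111111", "4444444"))
#' @export
build_puf <- function(record) {
  record <- as.list(record)
  sev <- rescale_level_ratings(record_cols(record, "vas_%s_l2"),
                               record_cols(record, "vas_%s_l3"))
  w <- normalize_weights(record_cols(record, "weight_%s"))
  anchor <- compute_anchor(as.character(record$anchor_branch),
                           as.numeric(record$anchor_vas))
  dec <- w * sev * (1 - anchor)   # rows recycle w over the 4 level columns
  structure(
    list(id = if (is.null(record$id)) NA_character_ else as.character(record$id),
         anchor = anchor, weights = w, severities = sev, decrements = dec),
    class = "mobqol_puf"
  )
}

#' Build personal utility functions for a respondent table
#'
#' @param records Data.frame of respondent records (one row each).
#' @return A list of `mobqol_puf` objects.
#' @export
build_pufs <- function(records) {
  lapply(seq_len(nrow(records)), function(i) build_puf(records[i, ]))
}

#' Evaluate a personal utility function on health states
#'
#' @param puf A `mobqol_puf` from [build_puf()].
#' @param state Character vector of 7-digit state indices.
#' @return Numeric vector of utilities; "1111111" scores 1 and "4444444"
#'   scores the respondent's anchor.
#' @export
puf_utility <- function(puf, state) {
  stopifnot(inherits(puf, "mobqol_puf"))
  decrement_utility(puf$decrements, state)
}

# shared evaluator: u = 1 - sum_d dec[d, level_d]
decrement_utility <- function(dec, state) {
  lev <- parse_state_index(state)
  n <- nrow(lev)
  idx <- cbind(rep(seq_len(n_dims), each = n), as.vector(lev))
  1 - rowSums(matrix(dec[idx], nrow = n))
}

#' @export
print.mobqol_puf <- function(x, ...) {
  cat("MobQoL-7D personal utility function",
      if (!is.na(x$id)) sprintf("(id: %s)", x$id) else "", "\n")
  cat(sprintf("  anchor (utility of 4444444): %.4f\n", x$anchor))
  cat("  normalised weights:\n")
  print(round(x$weights, 4))
  cat("  decrements (dimension x level):\n")
  print(round(x$decrements, 4))
  invisible(x)
}

#' Quality-control flags for a respondent record
#'
#' Screens one record for the inconsistencies that would have led to
#' exclusion in an OPUF survey, without dropping anything itself:
#'
#' * `RANGE_VIOLATION` -- any VAS or weight outside \[0, 100\], or an
#'   unparseable own state / anchoring branch;
#' * `ALL_ZERO_WEIGHTS` -- every swing weight zero (no usable preferences);
#' * `NONMONOTONE_LEVELS` -- some dimension rated with level 2 below level 3
#'   (milder level placed worse than the more severe one);
#' * `INVERTED_GLOBAL` -- the raw responses imply the best state is worse
#'   than the worst state (possible only with out-of-range values, e.g. a
#'   worst-preferred anchoring VAS above 100).
#'
#' Which flags trigger exclusion is a downstream policy decision; see
#' [read_respondents()].
#'
#' @param record One-row data.frame or named list in the respondent schema.
#' @return Character vector of flags (possibly empty).
#' @export
validate_respondent <- function(record) {
  record <- as.list(record)
  flags <- character(0)
  l2 <- suppressWarnings(record_cols(record, "vas_%s_l2"))
  l3 <- suppressWarnings(record_cols(record, "vas_%s_l3"))
  w <- suppressWarnings(record_cols(record, "weight_%s"))
  av <- suppressWarnings(as.numeric(record$anchor_vas))
  branch <- as.character(record$anchor_branch)

  numbers <- c(l2, l3, w, av)
  branch_ok <- length(branch) == 1L && branch %in% c("worst", "dead")
  state_ok <- !is.null(record$state) &&
    !inherits(try(parse_state_index(as.character(record$state)),
                  silent = TRUE), "try-error")
  if (anyNA(numbers) || any(numbers < 0) || any(numbers > 100) ||
      !branch_ok || !state_ok)
    flags <- c(flags, "RANGE_VIOLATION")
  if (!anyNA(w) && all(w == 0))
    flags <- c(flags, "ALL_ZERO_WEIGHTS")
  if (!anyNA(l2) && !anyNA(l3) && any(l2 < l3))
    flags <- c(flags, "NONMONOTONE_LEVELS")

  # implied global ordering, computed from the raw (un-capped, un-clamped)
  # responses: u(best) = 1 must exceed u(worst) = anchor
  if (branch_ok && length(av) == 1L && !is.na(av)) {
    raw_anchor <- if (branch == "worst") av / 100 else
      if (av >= 100) -Inf else -av / (100 - av)
    if (raw_anchor > 1)
      flags <- c(flags, "INVERTED_GLOBAL")
  }
  unique(flags)
}

#' Quality-control flags for a respondent table
#'
#' @param records Data.frame of respondent records.
#' @return A list of character vectors, one per row (empty = clean).
#' @export
validate_respondents <- function(records) {
  lapply(seq_len(nrow(records)), function(i) validate_respondent(records[i, ]))
}
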