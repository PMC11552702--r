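#' MobQoL-7D dimensions
#'
#' The seven dimensions of the MobQoL-7D descriptive system in canonical
#' order: Accessibility (AC), Contribution (CO), Pain/Discomfort (PD),
#' Independence (IN), Self-Esteem (SE), Mood/Emotions (ME) and Anxiety (AX).
#' Health-state indices carry one digit per dimension in this order.
#'
#' @return A data.frame with columns `code`, `label` and `position` (1--7).
#' @examples
#' mobqol_dimensions()
#' @export
mobqol_dimensions <- function() {
  data.frame(
    code = c("AC", "CO", "PD", "IN", "SE", "ME", "AX"),
    label = c("Accessibility", "Contribution", "Pain/Discomfort",
              "Independence", "Self-Esteem", "Mood/Emotions", "Anxiety"),
    position = 1:7,
    stringsAsFactors = FALSE
  )
}

# canonical dimension codes, used throughout for row/column names
dim_codes <- function() c("AC", "CO", "PD", "IN", "SE", "ME", "AX")

n_dims <- 7L
n_levels <- 4L

#' Parse MobQoL-7D health-state indices
#'
#' A health state is written as a 7-digit string, one digit per dimension in
#' the canonical order AC, CO, PD, IN, SE, ME, AX, each digit a severity
#' level in 1 (no problems) to 4 (extreme problems). `"1111111"` is full
#' mobility-related quality of life; `"4444444"` is the worst state.
#'
#' @param index Character vector of 7-digit state indices.
#' @return An integer matrix with one row per state and columns named by
#'   dimension code; each entry is a level in 1--4. Row names are the
#'   original indices.
#' @examples
#' parse_state_index("1112111")
#' @seealso [format_state_index()], [enumerate_states()]
#' @export
parse_state_index <- function(index) {
  if (length(index) == 0L) {
    m <- matrix(integer(0), ncol = n_dims, dimnames = list(NULL, dim_codes()))
    return(m)
  }
  index <- as.character(index)
  bad_len <- which(nchar(index) != n_dims | is.na(index))
  if (length(bad_len)) {
    stop(sprintf(
      "state index must be exactly 7 characters: element %d is '%s' (%d characters)",
      bad_len[1], index[bad_len[1]], nchar(index[bad_len[1]])
    ), call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(index, "", fixed = TRUE), use.names = FALSE),
                  ncol = n_dims, byrow = TRUE)
  ok <- chars %in% c("1", "2", "3", "4")
  if (!all(ok)) {
    bad <- which(!matrix(ok, ncol = n_dims), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "state index '%s': character '%s' at position %d is not a level in 1-4",
      index[bad[["row"]]], chars[bad[["row"]], bad[["col"]]], bad[["col"]]
    ), call. = FALSE)
  }
  m <- matrix(as.integer(chars), ncol = n_dims,
              dimnames = list(index, dim_codes()))
  m
}

#' Format health-state level matrices back to 7-digit indices
#'
#' Inverse of [parse_state_index()].
#'
#' @param levels Integer matrix (or vector of length 7) of levels in 1--4,
#'   columns in canonical dimension order.
#' @return Character vector of 7-digit indices.
#' @export
format_state_index <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  if (ncol(levels) != n_dims)
    stop("'levels' must have 7 columns", call. = FALSE)
  storage.mode(levels) <- "integer"
  if (any(is.na(levels)) || any(levels < 1L) || any(levels > 4L))
    stop("levels must be integers in 1-4", call. = FALSE)
  do.call(paste0, as.data.frame(levels))
}

#' Enumerate the MobQoL-7D state space
#'
#' All 4^7 = 16,384 distinct health states, each exactly once, in
#' lexicographic order of the 7-digit index ("1111111" first, "4444444"
#' last).
#'
#' @return Character vector of 16,384 state indices.
#' @examples
#' length(enumerate_states())
#' @export
enumerate_states <- function() {
  g <- expand.grid(rep(list(1:4), n_dims))[, n_dims:1]
  sort(do.call(paste0, g))
}

#' Severity score of a health state
#'
#' The sum of the seven dimension levels, ranging from 7 (no problems on any
#' dimension) to 28 (extreme problems on all). A simple ordinal summary of
#' overall impairment; it carries no preference weighting.
#'
#' @param state Character vector of 7-digit state indices.
#' @return Integer vector of severity scores in 7--28.
#' @examples
#' severity_score(c("1111111", "4444444", "1112111"))
#' @export
severity_score <- function(state) {
  as.integer(rowSums(parse_state_index(state)))
}
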