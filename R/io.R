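# Respondent CSV schema, readers/writers and QC exclusion policy.
#
# Columns: id, sample, state, vas_<DIM>_l2 and vas_<DIM>_l3 for each of the
# seven dimension codes, weight_<DIM> for each, anchor_branch (worst|dead),
# anchor_vas, gender, age_band, employment, ethnicity. Decimal point '.',
# UTF-8, header required.

respondent_columns <- function() {
  c("id", "sample", "state",
    as.vector(rbind(sprintf("vas_%s_l2", dim_codes()),
                    sprintf("vas_%s_l3", dim_codes()))),
    sprintf("weight_%s", dim_codes()),
    "anchor_branch", "anchor_vas", "gender", "age_band",
    "employment", "ethnicity")
}

#' Write respondent records to CSV
#'
#' Stable column order; [read_respondents()] round-trips the table.
#'
#' @param records Data.frame of respondent records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(records, path) {
  cols <- respondent_columns()
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read respondent records from CSV
#'
#' Reads the respondent schema, attaches QC flags from
#' [validate_respondent()] as a `qc_flags` list-column, and applies the
#' exclusion policy:
#'
#' * `"paper"` (default) -- drop rows flagged `RANGE_VIOLATION`,
#'   `ALL_ZERO_WEIGHTS` or `INVERTED_GLOBAL` (the inconsistencies an OPUF
#'   data check would remove); `NONMONOTONE_LEVELS` rows are kept;
#' * `"keep-all"` -- keep every row, flags attached.
#'
#' Exclusion counts are reported via `message()`.
#'
#' @param path CSV file in the respondent schema.
#' @param policy `"paper"` or `"keep-all"`.
#' @return Data.frame of respondent records with a `qc_flags` list-column;
#'   attribute `n_excluded` gives the number of dropped rows.
#' @export
read_respondents <- function(path, policy = c("paper", "keep-all")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(state = "character"))
  missing <- setdiff(respondent_columns(), names(df))
  if (length(missing))
    stop("input is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$qc_flags <- validate_respondents(df)
  exclude_on <- c("RANGE_VIOLATION", "ALL_ZERO_WEIGHTS", "INVERTED_GLOBAL")
  drop <- if (policy == "paper")
    vapply(df$qc_flags, function(f) any(f %in% exclude_on), logical(1))
  else rep(FALSE, nrow(df))
  n_flagged <- sum(lengths(df$qc_flags) > 0)
  message(sprintf(
    "read %d respondents from %s: %d flagged, %d excluded (policy = %s)",
    nrow(df), basename(path), n_flagged, sum(drop), policy))
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}

# provenance record written next to every CLI output
write_provenance <- function(dir, command, args, seed) {
  obj <- list(command = command, args = as.list(args),
              seed = if (is.null(seed)) NA else as.integer(seed),
              package = "mobqol7d",
              package_version = as.character(utils::packageVersion("mobqol7d")),
              r_version = as.character(getRversion()))
  jsonlite::write_json(obj, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Write a preference profile to JSON
#'
#' @param profile A `mobqol_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  obj <- list(
    name = profile$name,
    dimensions = dim_codes(),
    level_ratings = lapply(seq_len(n_dims), function(d)
      as.list(profile$level_ratings[d, ])),
    weights = lapply(seq_len(n_dims), function(d)
      as.list(profile$weights[d, ])),
    anchoring = profile$anchoring,
    own_state = lapply(seq_len(n_dims), function(d)
      unname(profile$own_state[d, ])),
    demographics = lapply(profile$demographics, as.list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a preference profile from JSON
#'
#' @param path File written by [write_profile()].
#' @return A `mobqol_profile`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_named_mat <- function(x, cols) {
    m <- if (is.matrix(x)) x else if (is.data.frame(x)) as.matrix(x)
         else do.call(rbind, x)
    storage.mode(m) <- "double"
    dimnames(m) <- list(dim_codes(), cols)
    m
  }
  profile <- structure(list(
    name = obj$name,
    level_ratings = as_named_mat(obj$level_ratings,
                                 c("l2_mean", "l2_sd", "l3_mean", "l3_sd")),
    weights = as_named_mat(obj$weights, c("mean", "sd")),
    anchoring = as.list(obj$anchoring),
    own_state = as_named_mat(obj$own_state, paste0("l", 1:4)),
    demographics = lapply(obj$demographics, unlist)
  ), class = "mobqol_profile")
  validate_profile(profile)
  profile
}
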