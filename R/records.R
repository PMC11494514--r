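#' Functional groups of flower visitors
#'
#' The ten functional groups used to classify flower visitors: bumblebees,
#' honeybees, solitary bees, hoverflies, other flies, beetles, stinkbugs and
#' cicadas, butterflies, moths, and a residual "others" group (ants,
#' mosquitos, Orthoptera, Mecoptera, Trichoptera).
#'
#' @format Character vector of length 10.
#' @export
pollinator_groups <- c(
  "bumblebees", "honeybees", "solitary_bees", "hoverflies", "other_flies",
  "beetles", "stinkbugs_cicadas", "butterflies", "moths", "others"
)

.trim <- function(x) {
  x <- as.character(x)
  gsub("^\\s+|\\s+$", "", x)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a data frame of visitation events
#'
#' Checks column presence, trims whitespace from labels, and enforces the
#' record invariants: non-empty specimen ids and taxon labels, functional
#' group within the ten-group vocabulary. Duplicate rows are retained: they
#' are sampling events, and only collapse to a single link when a binary
#' matrix is built.
#'
#' @param df data frame with columns `census`, `meadow`, `plant`,
#'   `specimen_id`, `pollinator`, `group`.
#' @return The validated data frame (labels trimmed), one row per event.
#' @export
as_visit_records <- function(df) {
  .require_columns(df, c("census", "meadow", "plant", "specimen_id",
                         "pollinator", "group"), "visit records")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("meadow", "plant", "specimen_id", "pollinator", "group")) {
    df[[col]] <- .trim(df[[col]])
  }
  if (any(df$specimen_id == "")) {
    stop("visit records: empty specimen_id in row(s) ",
         paste(utils::head(which(df$specimen_id == ""), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$plant == "") || any(df$pollinator == "")) {
    stop("visit records: empty plant or pollinator label", call. = FALSE)
  }
  bad <- setdiff(unique(df$group), pollinator_groups)
  if (length(bad) > 0L) {
    stop(sprintf(
      "visit records: unknown functional group(s): %s. Allowed: %s",
      paste(bad, collapse = ", "), paste(pollinator_groups, collapse = ", ")),
      call. = FALSE)
  }
  df
}

#' Read visitation events from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row and columns
#'   `census`, `meadow`, `plant`, `specimen_id`, `pollinator`, `group`.
#' @return Data frame of validated visitation events (see
#'   [as_visit_records()]).
#' @export
read_visit_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_visit_records(df)
}

#' Validate a data frame of pollen-load records
#'
#' One row per (specimen, plant) pollen observation: `grains` is the number
#' of grains of that plant identified on that specimen's body. Rows with the
#' same specimen and plant are summed at matrix construction.
#'
#' @param df data frame with columns `specimen_id`, `pollinator`, `period`,
#'   `plant`, `grains`.
#' @return The validated data frame.
#' @export
as_pollen_records <- function(df) {
  .require_columns(df, c("specimen_id", "pollinator", "period", "plant",
                         "grains"), "pollen records")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("specimen_id", "pollinator", "period", "plant")) {
    df[[col]] <- .trim(df[[col]])
  }
  if (any(df$specimen_id == "") || any(df$plant == "") ||
      any(df$pollinator == "")) {
    stop("pollen records: empty specimen_id, plant or pollinator label",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$period), c("diurnal", "nocturnal"))
  if (length(bad) > 0L) {
    stop("pollen records: period must be 'diurnal' or 'nocturnal', found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$grains <- as.numeric(df$grains)
  if (any(!is.finite(df$grains)) || any(df$grains < 0) ||
      any(df$grains != round(df$grains))) {
    stop("pollen records: grains must be nonnegative integers", call. = FALSE)
  }
  df$grains <- as.integer(df$grains)
  df
}

#' Read pollen-load records from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row and columns
#'   `specimen_id`, `pollinator`, `period`, `plant`, `grains`.
#' @return Data frame of validated pollen records (see
#'   [as_pollen_records()]).
#' @export
read_pollen_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_pollen_records(df)
}
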