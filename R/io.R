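CANONICAL_CHOICE_COLUMNS <- c(
  "participant_id", "condition", "assigned_predictivity", "round_index",
  "round_kind", "cue_position", "superior_position", "cue_predictive",
  "historical_predictivity", "chosen_position", "chose_cue_option",
  "realised_payoff"
)

#' Column map for externally deposited choice data
#'
#' Deposited datasets rarely use this package's column names. A column
#' map pairs each canonical analysis column with its name in the source
#' file, plus optional value recodings (e.g. condition or position
#' labels). The identity map is the default. Canonical columns that are
#' derivable (`cue_predictive` from the cue and superior positions,
#' `historical_predictivity` from the flags) may be omitted from the
#' source; they are then recomputed.
#'
#' @param columns Named character vector, `canonical = source`. Only
#'   names in the canonical schema are allowed.
#' @param recode Named list: for each canonical column, a named character
#'   vector `source_value = canonical_value`.
#' @return A `column_map` object.
#' @export
#' @examples
#' column_map(columns = c(participant_id = "subj", condition = "arm"),
#'            recode = list(condition = c(A = "decoy", B = "default")))
column_map <- function(columns = character(), recode = list()) {
  if (length(columns) > 0) {
    stopifnot(!is.null(names(columns)),
              all(names(columns) %in% CANONICAL_CHOICE_COLUMNS))
  }
  full <- stats::setNames(CANONICAL_CHOICE_COLUMNS, CANONICAL_CHOICE_COLUMNS)
  full[names(columns)] <- columns
  structure(list(columns = full, recode = recode), class = "column_map")
}

#' Write / read the canonical long-format choice dataset
#'
#' Comma-separated, UTF-8, header row, period decimal separator.
#'
#' @param data Choice dataset (one row per participant x round).
#' @param path File path.
#' @return `write_choice_data()` returns `path` invisibly.
#' @export
write_choice_data <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a deposited choice dataset through a column map
#'
#' Reads a long-format CSV, renames and recodes columns to the canonical
#' schema, and validates the derived quantities: the cue-predictive flag
#' is recomputed from the cue and superior positions, and the historical
#' predictivity is recomputed from the flags in round order per
#' participant, whenever the ingredient columns are present. If the file
#' also carries those columns, recomputed and provided values are
#' compared and any disagreement reported as a warning with a mismatch
#' count; missing derivable columns are filled in silently.
#'
#' @param path CSV file path.
#' @param map A [column_map()].
#' @return Canonical choice tibble.
#' @export
read_study_data <- function(path, map = column_map()) {
  stopifnot(inherits(map, "column_map"))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- map$columns
  present <- cols[cols %in% names(raw)]
  derivable <- c("cue_predictive", "historical_predictivity", "chose_cue_option")
  required <- setdiff(CANONICAL_CHOICE_COLUMNS, derivable)
  missing_src <- cols[setdiff(required, names(present))]
  if (length(missing_src) > 0) {
    stop("source file lacks mapped columns: ",
         paste(sprintf("%s (for %s)", missing_src, names(missing_src)),
               collapse = ", "))
  }
  data <- raw[, unname(present)]
  names(data) <- names(present)
  for (col in names(map$recode)) {
    if (col %in% names(data)) {
      rc <- map$recode[[col]]
      hit <- data[[col]] %in% names(rc)
      data[[col]][hit] <- unname(rc[as.character(data[[col]][hit])])
    }
  }
  data <- data[order(data$participant_id, data$round_index), ]

  cp_new <- as.integer(data$cue_position == data$superior_position)
  if ("cue_predictive" %in% names(data)) {
    bad <- sum(data$cue_predictive != cp_new, na.rm = TRUE)
    if (bad > 0) {
      warning(sprintf(
        "cue_predictive disagrees with cue/superior positions on %d of %d rows; using recomputed values",
        bad, nrow(data)))
    }
  }
  data$cue_predictive <- cp_new

  h_new <- unlist(lapply(split(data$cue_predictive, data$participant_id),
                         running_predictivity), use.names = FALSE)
  if ("historical_predictivity" %in% names(data)) {
    diff <- abs(data$historical_predictivity - h_new)
    bad <- sum(diff > 1e-8, na.rm = TRUE)
    if (bad > 0) {
      warning(sprintf(
        "historical_predictivity disagrees with its recomputation on %d of %d rows (max |diff| = %.4g); using recomputed values",
        bad, nrow(data), max(diff, na.rm = TRUE)))
    }
  }
  data$historical_predictivity <- h_new

  if (!"chose_cue_option" %in% names(data)) {
    data$chose_cue_option <- as.integer(data$chosen_position == data$cue_position)
  }
  as_tibble(data[, CANONICAL_CHOICE_COLUMNS])
}
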