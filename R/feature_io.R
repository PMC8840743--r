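#' Feature-table, standards-table and response-factor-table I/O
#'
#' All tables are comma-separated UTF-8 text with a "." decimal mark. An
#' empty `area`/`rt` cell means the feature was not detected at that
#' dilution; absence of `area` and `rt` always go together.
#'
#' @name table_io
NULL

FEATURE_COLUMNS <- c("compound_id", "mode", "ph", "dilution_factor",
                     "area", "rt", "mz", "na_adduct")
STANDARDS_COLUMNS <- c("compound_id", "dilution_factor", "concentration_M")
RF_COLUMNS <- c("compound_id", "mode", "ph", "rf", "log_rf",
                "mean_rt", "n_points_used")

# Validate a peak-record data frame; returns it normalized.
validate_feature_table <- function(df) {
  missing_cols <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("feature table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, FEATURE_COLUMNS]
  df$compound_id <- as.character(df$compound_id)
  df$mode <- as.character(df$mode)
  for (col in c("ph", "dilution_factor", "area", "rt", "mz")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$na_adduct <- as.logical(df$na_adduct)
  if (nrow(df) > 0) {
    assert_condition(df$mode, df$ph)
    if (any(is.na(df$dilution_factor) | df$dilution_factor < 1)) {
      stop("dilution_factor must be >= 1 for every record", call. = FALSE)
    }
    if (any(is.na(df$area) != is.na(df$rt))) {
      stop("area and rt must be absent together (not-detected records)",
           call. = FALSE)
    }
    if (any(!is.na(df$area) & df$area <= 0)) {
      stop("detected records must have positive area", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

# Deterministic row order: compound, condition, dilution.
sort_feature_table <- function(df) {
  if (nrow(df) == 0) return(df)
  ord <- order(df$compound_id, condition_order(df$mode, df$ph),
               df$dilution_factor)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a peak-record feature table from CSV
#'
#' @param path path to a CSV file with header columns `compound_id`, `mode`,
#'   `ph`, `dilution_factor`, `area`, `rt`, `mz`, `na_adduct`.
#' @return A validated data frame of peak records; empty `area`/`rt` cells
#'   become `NA` (not detected).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  validate_feature_table(df)
}

#' Write a peak-record feature table to CSV
#'
#' Rows are sorted by compound id, condition and dilution factor so output
#' is deterministic; not-detected cells are written empty.
#'
#' @param records data frame of peak records (see [read_feature_table()])
#' @param path output path
#' @export
write_feature_table <- function(records, path) {
  records <- sort_feature_table(validate_feature_table(records))
  write_csv_plain(records, path)
}

#' Read a standards concentration table (compound_id, dilution_factor,
#' concentration_M)
#' @param path CSV path
#' @export
read_standards_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STANDARDS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("standards table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, STANDARDS_COLUMNS]
  df$compound_id <- as.character(df$compound_id)
  if (nrow(df) > 0 && any(df$concentration_M <= 0)) {
    stop("standard concentrations must be positive", call. = FALSE)
  }
  df
}

#' Write a standards concentration table
#' @param standards data frame with columns compound_id, dilution_factor,
#'   concentration_M
#' @param path output path
#' @export
write_standards_table <- function(standards, path) {
  standards <- standards[, STANDARDS_COLUMNS]
  standards <- standards[order(standards$compound_id,
                               standards$dilution_factor), , drop = FALSE]
  write_csv_plain(standards, path)
}

#' Read a response-factor table (compound_id, mode, ph, rf, log_rf, mean_rt,
#' n_points_used)
#' @param path CSV path
#' @export
read_rf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RF_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("response-factor table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, RF_COLUMNS]
  df$compound_id <- as.character(df$compound_id)
  if (nrow(df) > 0) assert_condition(df$mode, df$ph)
  df
}

#' Write a response-factor table
#' @param rf_table data frame with the response-factor columns
#' @param path output path
#' @export
write_rf_table <- function(rf_table, path) {
  rf_table <- rf_table[, RF_COLUMNS]
  if (nrow(rf_table) > 0) {
    rf_table <- rf_table[order(rf_table$compound_id,
                               condition_order(rf_table$mode, rf_table$ph)), ,
                         drop = FALSE]
  }
  write_csv_plain(rf_table, path)
}

# CSV writer: 15 significant digits (round-trip stable for doubles at the
# declared precision), empty cell for NA, no row names.
write_csv_plain <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      x <- sprintf("%.15g", out[[col]])
      x[is.na(out[[col]])] <- NA_character_
      out[[col]] <- x
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
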