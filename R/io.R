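## CSV readers/writers for the pipeline's file interfaces. Headers are fixed;
## timestamps are integer milliseconds UTC, dates ISO-8601, and absent values
## (ymrs for controls, median IKD of filtered windows) are empty strings.

write_csv_exact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_validation("%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation("%s file %s lacks column(s): %s", what, path,
                    paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a generated cohort to CSV files
#'
#' Emits `subjects.csv`, `keypresses.csv`, `dtmt.csv`, `mood.csv` and
#' `ptmt.csv` with the pipeline's fixed schemas.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             keypresses = file.path(dir, "keypresses.csv"),
             dtmt = file.path(dir, "dtmt.csv"),
             mood = file.path(dir, "mood.csv"),
             ptmt = file.path(dir, "ptmt.csv"))
  write_csv_exact(cohort$roster, paths["subjects"])
  kp <- cohort$keypresses
  kp$timestamp_ms <- sprintf("%.0f", kp$timestamp_ms)
  write_csv_exact(kp, paths["keypresses"])
  dt <- cohort$dtmt
  dt$timestamp_ms <- sprintf("%.0f", dt$timestamp_ms)
  write_csv_exact(dt, paths["dtmt"])
  md <- cohort$mood
  md$date <- as.character(md$date)
  write_csv_exact(md, paths["mood"])
  write_csv_exact(cohort$ptmt, paths["ptmt"])
  invisible(paths)
}

#' Read the cohort CSV files
#'
#' @param dir directory containing `subjects.csv`, `keypresses.csv`,
#'   `dtmt.csv`, `mood.csv` and optionally `ptmt.csv`.
#' @return list with `roster`, `keypresses`, `dtmt`, `mood`, `ptmt` (or
#'   `NULL` if absent).
#' @export
read_cohort <- function(dir) {
  roster <- read_csv_checked(file.path(dir, "subjects.csv"),
                             c("subject_id", "age", "diagnosis", "gender"),
                             "roster")
  keys <- read_csv_checked(file.path(dir, "keypresses.csv"),
                           c("subject_id", "timestamp_ms", "category"),
                           "keypress")
  keys$timestamp_ms <- as.numeric(keys$timestamp_ms)
  dtmt <- read_csv_checked(file.path(dir, "dtmt.csv"),
                           c("subject_id", "timestamp_ms",
                             "completion_time_s", "wrong_moves",
                             "variant_id", "slot"), "dTMT-B")
  dtmt$timestamp_ms <- as.numeric(dtmt$timestamp_ms)
  mood <- read_csv_checked(file.path(dir, "mood.csv"),
                           c("subject_id", "date", "hdrs17"), "mood")
  mood$date <- as.Date(mood$date)
  ppath <- file.path(dir, "ptmt.csv")
  ptmt <- if (file.exists(ppath)) {
    read_csv_checked(ppath, c("subject_id", "occasion", "time_s"),
                     "paper TMT-B")
  } else NULL
  list(roster = roster, keypresses = keys, dtmt = dtmt, mood = mood,
       ptmt = ptmt)
}

#' Write the windows table
#' @param windows output of [compute_window_features()].
#' @param path output CSV path.
#' @export
write_windows <- function(windows, path) {
  df <- windows[, c("subject_id", "dtmt_timestamp_ms", "window_start_ms",
                    "window_end_ms", "n_keypresses", "n_valid_transitions",
                    "median_ikd_s")]
  df$dtmt_timestamp_ms <- sprintf("%.0f", df$dtmt_timestamp_ms)
  df$window_start_ms <- sprintf("%.0f", df$window_start_ms)
  df$window_end_ms <- sprintf("%.0f", df$window_end_ms)
  write_csv_exact(df, path)
}

#' Read a windows table written by [write_windows()]
#' @param path CSV path.
#' @export
read_windows <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "dtmt_timestamp_ms",
                                 "window_start_ms", "window_end_ms",
                                 "n_keypresses", "n_valid_transitions",
                                 "median_ikd_s"), "windows")
  for (col in c("dtmt_timestamp_ms", "window_start_ms", "window_end_ms",
                "median_ikd_s")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
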