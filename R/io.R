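#' Read and write the occasion-level CSV dialect
#'
#' One row per scheduled vaccine occasion. Core columns: `occasion_id`,
#' `parent_id`, `child_id`, `clinic_id`, `schedule_point`, `due_date`
#' (integer day index from trial start, day 0), `receipt_day` (signed
#' offset from the due date; empty when there is no receipt record),
#' `arm_framing`, `arm_timing`, `epoch`, `is_index`. Any further columns
#' (eligibility, SMS events, endpoint status) are carried through
#' unchanged. The round trip `read(write(x))` preserves every field
#' exactly: days are integers and missing receipts are empty strings.
#'
#' @param occasions Occasion data frame; if it has an `arm` column, framing
#'   and timing columns are derived from it.
#' @param path CSV file path.
#' @return `write_occasions_csv()` returns `path` invisibly;
#'   `read_occasions_csv()` returns the occasion data frame with an `arm`
#'   label column rebuilt from framing/timing.
#' @export
write_occasions_csv <- function(occasions, path) {
  x <- occasions
  if ("arm" %in% names(x) &&
      !all(c("arm_framing", "arm_timing") %in% names(x))) {
    at <- arm_table()
    k <- match(x$arm, at$arm)
    x$arm_framing <- as.character(at$framing[k])
    x$arm_timing <- as.character(at$timing[k])
    x$arm <- NULL
  }
  lead <- intersect(c("occasion_id", "parent_id", "child_id", "clinic_id",
                      "schedule_point", "due_date", "receipt_day",
                      "arm_framing", "arm_timing", "epoch", "is_index"),
                    names(x))
  x <- x[, c(lead, setdiff(names(x), lead)), drop = FALSE]
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_occasions_csv
#' @export
read_occasions_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(occasion_id = "character",
                                      parent_id = "character",
                                      child_id = "character",
                                      clinic_id = "character"))
  for (col in c("schedule_point", "due_date", "receipt_day", "epoch"))
    if (col %in% names(x)) x[[col]] <- as.integer(x[[col]])
  if (all(c("arm_framing", "arm_timing") %in% names(x))) {
    at <- arm_table()
    x$arm <- at$arm[match(paste(x$arm_framing, x$arm_timing),
                          paste(at$framing, at$timing))]
  }
  x
}

#' Write per-arm posterior summaries
#'
#' @param summary An [summarise_arms()] data frame.
#' @param path Output path; `.json` writes JSON, anything else CSV (full
#'   precision).
#' @return `path`, invisibly.
#' @export
write_arm_summary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(summary, path, row.names = FALSE)
  }
  invisible(path)
}

#' Append interim decisions to a JSON-lines adaptation log
#'
#' Each line records one analysis: index, completed index occasions,
#' pooled and max-arm posterior probabilities, declaration flags, and the
#' per-arm targets in force afterwards.
#'
#' @param trial An `sms_trial` from [run_virtual_trial()].
#' @param path Log file (appended to).
#' @return `path`, invisibly.
#' @export
append_adaptation_log <- function(trial, path) {
  if (is.null(trial$interims)) return(invisible(path))
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(nrow(trial$interims))) {
    row <- as.list(trial$interims[i, ])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
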