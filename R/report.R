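#' Arm-by-arm report of index vaccinations
#'
#' Builds the familiar trial-report layout: one row per timing-by-framing
#' combination (control first) with the number of index vaccinations, the
#' number and displayed proportion vaccinated on time, and counts in the
#' receipt-day bins (-14, 0], (0, 7], (7, 28] whose endpoints are the three
#' reminder timings. Day -14 receipts fall in the first bin, so the three
#' bins partition the on-time receipts and their counts sum to the on-time
#' count. A totals row closes the table.
#'
#' @param occasions Occasion-level data with `arm`, `is_index`, `status`
#'   and `receipt_offset` columns (e.g. the trial CSV dialect).
#' @return Data frame of class `sms_table_one` with columns `timing`,
#'   `framing`, `index_n`, `ontime_n`, `ontime_prop` (2 dp display
#'   rounding), `bin_m14_0`, `bin_0_7`, `bin_7_28`.
#' @export
table_one <- function(occasions) {
  at <- arm_table()
  occ <- occasions[occasions$is_index %in% TRUE &
                     occasions$status %in% c("ontime", "not_ontime"), ,
                   drop = FALSE]
  if (nrow(occ) && any(is.na(match(occ$arm, at$arm))))
    stop("occasion with endpoint but unknown arm", call. = FALSE)
  f <- factor(occ$arm, levels = at$arm)
  ontime <- occ$status == "ontime"
  off <- occ$receipt_offset
  bin1 <- ontime & off <= 0
  bin2 <- ontime & off > 0 & off <= 7
  bin3 <- ontime & off > 7 & off <= 28
  cnt <- function(flag) as.integer(table(f[flag]))
  out <- data.frame(
    timing = as.character(at$timing),
    framing = as.character(at$framing),
    index_n = as.integer(table(f)),
    ontime_n = cnt(ontime),
    bin_m14_0 = cnt(bin1),
    bin_0_7 = cnt(bin2),
    bin_7_28 = cnt(bin3),
    stringsAsFactors = FALSE
  )
  out <- arm_report_rows(out)
  class(out) <- c("sms_table_one", "data.frame")
  out
}

#' @description `arm_report_rows()` finishes a count table (as above but
#'   without proportions/totals): it validates the bin partition, computes
#'   display proportions, and appends the totals row. Use it to render a
#'   table directly from printed counts.
#' @param counts Data frame with `timing`, `framing`, `index_n`,
#'   `ontime_n`, `bin_m14_0`, `bin_0_7`, `bin_7_28`.
#' @rdname table_one
#' @export
arm_report_rows <- function(counts) {
  stopifnot(all(c("timing", "framing", "index_n", "ontime_n", "bin_m14_0",
                  "bin_0_7", "bin_7_28") %in% names(counts)))
  bad <- counts$bin_m14_0 + counts$bin_0_7 + counts$bin_7_28 !=
    counts$ontime_n
  if (any(bad))
    stop("interval bins must partition the on-time count", call. = FALSE)
  tot <- data.frame(timing = "Total", framing = "",
                    index_n = sum(counts$index_n),
                    ontime_n = sum(counts$ontime_n),
                    bin_m14_0 = sum(counts$bin_m14_0),
                    bin_0_7 = sum(counts$bin_0_7),
                    bin_7_28 = sum(counts$bin_7_28),
                    stringsAsFactors = FALSE)
  out <- rbind(counts[, names(tot)], tot)
  out$ontime_prop <- ifelse(out$index_n > 0,
                            round(out$ontime_n / out$index_n, 2), NA_real_)
  out <- out[, c("timing", "framing", "index_n", "ontime_n", "ontime_prop",
                 "bin_m14_0", "bin_0_7", "bin_7_28")]
  rownames(out) <- NULL
  class(out) <- c("sms_table_one", "data.frame")
  out
}

#' Early-vaccination exclusion summary
#'
#' Occasions vaccinated more than 14 days before their due date were never
#' eligible for an SMS and are excluded from analysis. Reports the overall
#' excluded count with an integer-rounded percentage, and each schedule
#' point's share of the exclusions.
#'
#' @param occasions Occasion-level data with `status` (or `receipt_day`)
#'   and `schedule_point`.
#' @return List with `n_total`, `n_excluded`, `pct_excluded` (integer
#'   display rounding), and data frame `by_schedule_point`
#'   (`schedule_point`, `n`, `pct_of_excluded`).
#' @export
exclusion_summary <- function(occasions) {
  excl <- if ("status" %in% names(occasions))
    occasions$status %in% "excluded_early"
  else occasions$receipt_day < -14L & !is.na(occasions$receipt_day)
  n_total <- nrow(occasions)
  n_excl <- sum(excl)
  by_pt <- if (n_excl > 0) {
    t <- table(occasions$schedule_point[excl])
    data.frame(schedule_point = as.integer(names(t)),
               n = as.integer(t),
               pct_of_excluded = round(100 * as.integer(t) / n_excl),
               stringsAsFactors = FALSE)
  } else {
    data.frame(schedule_point = integer(0), n = integer(0),
               pct_of_excluded = numeric(0))
  }
  list(n_total = n_total, n_excluded = n_excl,
       pct_excluded = if (n_total > 0) round(100 * n_excl / n_total) else 0,
       by_schedule_point = by_pt)
}

format_or_cell <- function(median_or, cri_low, cri_high, pr_gt_1) {
  sprintf("%.2f (%.2f, %.2f) %.2f", median_or, cri_low, cri_high, pr_gt_1)
}

#' Odds-ratio grid across the five model structures
#'
#' Lays out posterior arm summaries from any subset of the five model
#' structures as a timing x framing grid, one column block per model, each
#' cell formatted `median (lower, upper) Pr(>1)` at the display precision
#' used in trial reports (ORs to 2 decimals). Margin rows ("All framings")
#' and the all-timings block are populated only by the models to which
#' they apply (timing-only / shared and framing-only / shared
#' respectively); a missing model structure leaves an explicit `"-"` gap,
#' never a silent omission.
#'
#' @param summaries Named list of [summarise_arms()] data frames; names
#'   among `full`, `no_interaction`, `framing_only`, `timing_only`,
#'   `shared`.
#' @return Data frame of class `sms_table_two`: `timing`, `framing`, one
#'   character column per model structure.
#' @export
table_two <- function(summaries) {
  models <- c("full", "no_interaction", "framing_only", "timing_only",
              "shared")
  if (is.null(names(summaries)) ||
      !all(names(summaries) %in% models))
    stop("summaries must be a named list over the five model structures",
         call. = FALSE)
  framings <- c("all", "neutral", "positive", "risk", "social")
  timings <- c("all", "day-14", "day0", "day+7")
  grid <- expand.grid(framing = framings, timing = timings,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("timing", "framing")]

  cell <- function(model, timing, framing) {
    s <- summaries[[model]]
    if (is.null(s)) return("-")
    # which cells a structure populates
    want <- switch(model,
      full = timing != "all" && framing != "all",
      no_interaction = timing != "all" && framing != "all",
      framing_only = timing == "all" && framing != "all",
      timing_only = timing != "all" && framing == "all",
      shared = timing == "all" && framing == "all")
    if (!want) return("")
    rows <- s[(timing == "all" | s$timing == timing) &
                (framing == "all" | s$framing == framing), , drop = FALSE]
    if (!nrow(rows)) return("-")
    r <- rows[1L, ]
    format_or_cell(r$median_or, r$cri_low, r$cri_high, r$pr_gt_1)
  }
  for (m in models)
    grid[[m]] <- mapply(cell, m, grid$timing, grid$framing,
                        USE.NAMES = FALSE)
  class(grid) <- c("sms_table_two", "data.frame")
  grid
}

#' Write a report table as Markdown
#'
#' @param x A data frame (e.g. [table_one()] or [table_two()] output).
#' @param path Output file.
#' @return `path`, invisibly. Output is byte-identical for identical input.
#' @export
write_markdown_table <- function(x, path) {
  x <- as.data.frame(x)
  fmt <- vapply(x, function(col) format(col, trim = TRUE), character(nrow(x)))
  fmt <- rbind(colnames(x), rep("---", ncol(x)), fmt)
  lines <- apply(fmt, 1L, paste, collapse = " | ")
  writeLines(paste0("| ", lines, " |"), path)
  invisible(path)
}
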