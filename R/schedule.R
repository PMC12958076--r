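#' Screen occasions for SMS eligibility
#'
#' Applies the trial's screening filters to each scheduled occasion: the
#' parent must not have opted out of SMS contact, must have a mobile phone
#' number and a recorded name/date of birth, and the dose must not already
#' have been administered more than 14 days before its due date ("early
#' vaccination", which precedes the point at which any reminder could be
#' sent). Malformed or missing parent records yield ineligibility with a
#' reason code rather than an error.
#'
#' @param occasions Occasion data frame (columns `occasion_id`, `parent_id`,
#'   `due_date`; optional `early_vax` flag and/or `receipt_day` offset).
#' @param parents Parent data frame with `parent_id`, `opted_out`,
#'   `has_phone`, `has_name_dob` (missing columns are treated as clean).
#' @param as_of_day Screening day: receipts after this day are not yet
#'   visible. Default `Inf` (all known).
#' @return Data frame with `occasion_id`, `eligible` (logical) and `reasons`
#'   (comma-separated codes among `opted_out`, `missing_phone`,
#'   `missing_name_or_dob`, `early_vaccinated`; empty when eligible).
#' @export
screen_eligibility <- function(occasions, parents, as_of_day = Inf) {
  n <- nrow(occasions)
  m <- match(occasions$parent_id, parents$parent_id)
  getf <- function(col, default) {
    if (col %in% names(parents)) {
      v <- parents[[col]][m]
      v[is.na(v)] <- !default  # unknown parent: fail the check
      v
    } else rep(default, n)
  }
  opted <- getf("opted_out", FALSE)
  phone <- getf("has_phone", TRUE)
  named <- getf("has_name_dob", TRUE)
  bad_parent <- is.na(m)
  opted <- opted | bad_parent

  early <- rep(FALSE, n)
  if ("receipt_day" %in% names(occasions)) {
    vis <- !is.na(occasions$receipt_day) &
      (occasions$due_date + occasions$receipt_day) <= as_of_day
    early <- early | (vis & occasions$receipt_day < -14L)
  }
  if ("early_vax" %in% names(occasions))
    early <- early | (occasions$early_vax %in% TRUE &
                        (occasions$due_date - 15L) <= as_of_day)

  reasons <- character(n)
  add <- function(reasons, flag, code)
    ifelse(flag, ifelse(nzchar(reasons), paste(reasons, code, sep = ","),
                        code), reasons)
  reasons <- add(reasons, opted, "opted_out")
  reasons <- add(reasons, !phone, "missing_phone")
  reasons <- add(reasons, !named, "missing_name_or_dob")
  reasons <- add(reasons, early, "early_vaccinated")

  data.frame(occasion_id = occasions$occasion_id,
             eligible = !nzchar(reasons),
             reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Most recent prior dose receipt per occasion
#'
#' For each occasion, the absolute day of the same child's latest earlier
#' vaccine receipt (`NA` when none). Used for the minimum-interval
#' withholding rule.
#'
#' @param occasions Occasion data frame with `child_id`, `due_date` and
#'   `receipt_day` (offset from due date, `NA` = no record).
#' @return Numeric vector aligned with `occasions`.
#' @export
prior_dose_days <- function(occasions) {
  n <- nrow(occasions)
  out <- rep(NA_real_, n)
  if (n == 0L) return(out)
  ord <- order(occasions$child_id, occasions$due_date)
  child <- occasions$child_id[ord]
  abs_receipt <- occasions$due_date[ord] + occasions$receipt_day[ord]
  run_max <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && child[i] == child[i - 1L]) {
      prev <- run_max[i - 1L]
      cand <- abs_receipt[i - 1L]
      run_max[i] <- if (is.na(prev)) cand else
        if (is.na(cand)) prev else max(prev, cand)
    }
  }
  out[ord] <- run_max
  out
}

#' Schedule (or withhold) SMS reminders
#'
#' An SMS is planned at `due_date + timing offset` of the assigned arm and
#' withheld when (i) the vaccine is already recorded as given before the
#' planned message day, (ii) the child's previous dose was received less
#' than 28 days (the minimum interval between eligible doses) before this
#' occasion's due date, or (iii) the planned day falls in an optional
#' outage-suppression mask. Control occasions produce no SMS event and are a
#' contract error here.
#'
#' @param occasions Occasion data frame with `arm`, `due_date`, `child_id`
#'   and `receipt_day` columns.
#' @param suppress_days Optional integer vector of calendar days on which no
#'   SMS could be sent (server outages).
#' @return Data frame `occasion_id`, `planned_day`, `sent`,
#'   `withheld_reason` (`NA` when sent). Deterministic: rerunning on the
#'   same input yields the same events.
#' @export
schedule_sms <- function(occasions, suppress_days = NULL) {
  at <- arm_table()
  k <- match(occasions$arm, at$arm)
  if (anyNA(k)) stop("unknown arm label", call. = FALSE)
  if (any(at$framing[k] == "control"))
    stop("control occasions have no SMS event", call. = FALSE)
  planned <- occasions$due_date + at$timing_offset[k]

  receipt_abs <- occasions$due_date + occasions$receipt_day
  already <- !is.na(receipt_abs) & receipt_abs < planned
  prior <- prior_dose_days(occasions)
  interval <- !is.na(prior) & (occasions$due_date - prior) < 28
  outage <- if (is.null(suppress_days)) FALSE else planned %in% suppress_days

  reason <- rep(NA_character_, nrow(occasions))
  reason[outage] <- "outage"
  reason[interval] <- "min_interval_unmet"
  reason[already] <- "already_vaccinated"
  data.frame(occasion_id = occasions$occasion_id,
             planned_day = planned,
             sent = is.na(reason),
             withheld_reason = reason,
             stringsAsFactors = FALSE)
}

#' Ascertain the primary endpoint
#'
#' On-time vaccination is receipt within the closed window from 14 days
#' before the due date to 28 days after. Occasions vaccinated more than 14
#' days early are `excluded_early` (never SMS-eligible). Follow-up is
#' complete 28 days after the due date; an occasion with complete follow-up
#' and no visible receipt record is `not_ontime` (absence of a record counts
#' as failure — there is no missing outcome). Before follow-up completes the
#' status is `NA` unless a receipt already decides it.
#'
#' @param occasions Occasion data frame with `due_date` and `receipt_day`.
#' @param as_of_day Ascertainment day; receipts after it are invisible.
#'   Must be at least `due_date - 14` for every occasion.
#' @return Data frame `occasion_id`, `status`
#'   (`excluded_early` / `ontime` / `not_ontime` / `NA`),
#'   `followup_complete`, `receipt_offset`.
#' @export
ascertain_endpoint <- function(occasions, as_of_day = Inf) {
  if (any(as_of_day < occasions$due_date - 14L))
    stop("premature ascertainment: as_of_day precedes due_date - 14",
         call. = FALSE)
  off <- occasions$receipt_day
  visible <- !is.na(off) & (occasions$due_date + off) <= as_of_day
  off[!visible] <- NA_integer_
  complete <- as_of_day >= occasions$due_date + 28L

  status <- rep(NA_character_, nrow(occasions))
  status[complete] <- "not_ontime"
  status[!is.na(off) & off >= -14L & off <= 28L] <- "ontime"
  status[!is.na(off) & off < -14L] <- "excluded_early"
  data.frame(occasion_id = occasions$occasion_id,
             status = status,
             followup_complete = complete & TRUE,
             receipt_offset = off,
             stringsAsFactors = FALSE)
}

#' Mark each parent's index occasion
#'
#' The index occasion is a parent's first SMS-eligible scheduled occasion:
#' smallest due date, with ties broken by `child_id` then `occasion_id` so
#' the choice is deterministic and invariant to input row order. Exactly one
#' occasion per parent with any eligible occasion is flagged.
#'
#' @param occasions Occasion data frame.
#' @param eligible Logical vector aligned with `occasions` (e.g. from
#'   [screen_eligibility()]); defaults to `!occasions$early_vax`.
#' @return `occasions` with a logical `is_index` column.
#' @export
mark_index_occasions <- function(occasions,
                                 eligible = !occasions$early_vax) {
  n <- nrow(occasions)
  occasions$is_index <- rep(FALSE, n)
  if (n == 0L) return(occasions)
  idx <- which(eligible)
  if (!length(idx)) return(occasions)
  sub <- occasions[idx, c("parent_id", "due_date", "child_id", "occasion_id")]
  ord <- order(sub$parent_id, sub$due_date, sub$child_id, sub$occasion_id)
  first <- ord[!duplicated(sub$parent_id[ord])]
  occasions$is_index[idx[first]] <- TRUE
  occasions
}
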