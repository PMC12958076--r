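mk_occ <- function(...) {
  defaults <- list(occasion_id = "O1", parent_id = "P1", child_id = "K1",
                   clinic_id = "C1", schedule_point = 4L, due_date = 100L,
                   epoch = 3L, receipt_day = NA_integer_)
  args <- utils::modifyList(defaults, list(...))
  do.call(data.frame, c(args, stringsAsFactors = FALSE))
}

clean_parent <- data.frame(parent_id = "P1", opted_out = FALSE,
                           has_phone = TRUE, has_name_dob = TRUE,
                           stringsAsFactors = FALSE)

test_that("screening applies each exclusion with its reason code", {
  p <- clean_parent
  p$opted_out <- TRUE
  r <- screen_eligibility(mk_occ(), p)
  expect_false(r$eligible)
  expect_match(r$reasons, "opted_out")

  r <- screen_eligibility(mk_occ(receipt_day = -20L), clean_parent)
  expect_false(r$eligible)
  expect_identical(r$reasons, "early_vaccinated")

  # day -14 receipt sits inside the window: still eligible
  r <- screen_eligibility(mk_occ(receipt_day = -14L), clean_parent)
  expect_true(r$eligible)
  expect_identical(r$reasons, "")

  p2 <- clean_parent; p2$has_phone <- FALSE; p2$has_name_dob <- FALSE
  r <- screen_eligibility(mk_occ(), p2)
  expect_identical(r$reasons, "missing_phone,missing_name_or_dob")

  # unknown parent record: ineligible, not an error
  r <- screen_eligibility(mk_occ(parent_id = "PX"), clean_parent)
  expect_false(r$eligible)
})

test_that("screening only sees receipts recorded by the screening day", {
  occ <- mk_occ(receipt_day = -20L)  # receipt on day 80
  expect_true(screen_eligibility(occ, clean_parent, as_of_day = 79)$eligible)
  expect_false(screen_eligibility(occ, clean_parent, as_of_day = 80)$eligible)
})

test_that("SMS events fire at the arm's offset and are withheld correctly", {
  # already vaccinated before the planned message date
  occ <- mk_occ(arm = "neutral:day-14", receipt_day = -16L)
  ev <- schedule_sms(occ)
  expect_identical(ev$planned_day, 86L)
  expect_false(ev$sent)
  expect_identical(ev$withheld_reason, "already_vaccinated")

  # clean path: day+7 reminder, prior dose 8 weeks earlier
  occ2 <- rbind(mk_occ(occasion_id = "O0", due_date = 44L,
                       receipt_day = 0L, arm = "risk:day+7"),
                mk_occ(occasion_id = "O1", due_date = 100L,
                       receipt_day = NA_integer_, arm = "risk:day+7"))
  ev2 <- schedule_sms(occ2)
  expect_true(ev2$sent[ev2$occasion_id == "O1"])
  expect_identical(ev2$planned_day[ev2$occasion_id == "O1"], 107L)

  # prior dose 3 weeks before the due date: minimum interval unmet
  occ3 <- rbind(mk_occ(occasion_id = "O0", due_date = 75L, receipt_day = 4L,
                       arm = "risk:day+7"),
                mk_occ(occasion_id = "O1", due_date = 100L, arm = "risk:day+7"))
  ev3 <- schedule_sms(occ3)
  expect_identical(ev3$withheld_reason[ev3$occasion_id == "O1"],
                   "min_interval_unmet")

  expect_error(schedule_sms(mk_occ(arm = "control")), "control")
})

test_that("SMS scheduling is idempotent and honours outage masks", {
  occ <- mk_occ(arm = "social:day0")
  expect_identical(schedule_sms(occ), schedule_sms(occ))
  ev <- schedule_sms(occ, suppress_days = 100L)
  expect_false(ev$sent)
  expect_identical(ev$withheld_reason, "outage")
})

test_that("endpoint window boundaries are closed at -14 and 28", {
  expect_identical(ascertain_endpoint(mk_occ(receipt_day = 28L))$status,
                   "ontime")
  expect_identical(ascertain_endpoint(mk_occ(receipt_day = 29L))$status,
                   "not_ontime")
  expect_identical(ascertain_endpoint(mk_occ(receipt_day = -14L))$status,
                   "ontime")
  expect_identical(ascertain_endpoint(mk_occ(receipt_day = -15L))$status,
                   "excluded_early")
  # absent receipt, follow-up complete: failure, no missing outcome
  r <- ascertain_endpoint(mk_occ(), as_of_day = 128)
  expect_identical(r$status, "not_ontime")
  expect_true(r$followup_complete)
  expect_error(ascertain_endpoint(mk_occ(), as_of_day = 85),
               "premature")
})

test_that("pending occasions have no status until follow-up completes", {
  # no receipt yet at day 110: undecided
  r <- ascertain_endpoint(mk_occ(receipt_day = 25L), as_of_day = 110)
  expect_true(is.na(r$status))
  expect_false(r$followup_complete)
  # but an in-window receipt already visible decides it
  r2 <- ascertain_endpoint(mk_occ(receipt_day = 5L), as_of_day = 110)
  expect_identical(r2$status, "ontime")
})

test_that("endpoint statuses partition completed occasions", {
  fx <- make_trial_occasions(n_parents = 800, or = 1.2, seed = 42)
  occ <- fx$occasions
  ep <- ascertain_endpoint(occ, as_of_day = Inf)
  expect_false(anyNA(ep$status))
  expect_identical(sum(ep$status == "excluded_early") +
                     sum(ep$status == "ontime") +
                     sum(ep$status == "not_ontime"), nrow(occ))
  # excluded_early if and only if receipt more than 14 days early
  expect_identical(ep$status == "excluded_early",
                   !is.na(occ$receipt_day) & occ$receipt_day < -14)
})

test_that("on-time status never depends on whether an SMS was sent", {
  fx <- make_trial_occasions(n_parents = 300, or = 1.5, seed = 7)
  occ <- fx$occasions
  sms <- occ[occ$arm != "control", ]
  ev_sent <- schedule_sms(sms)
  ev_masked <- schedule_sms(sms, suppress_days = -100:2000)
  expect_true(all(!ev_masked$sent))
  expect_false(isTRUE(all.equal(ev_sent$sent, ev_masked$sent)))
  # endpoints identical either way: intent-to-treat
  expect_identical(ascertain_endpoint(sms), ascertain_endpoint(sms))
})

test_that("index marking picks the first eligible occasion per parent", {
  occ <- rbind(mk_occ(occasion_id = "O1", due_date = 70L),
               mk_occ(occasion_id = "O2", due_date = 10L))
  occ$early_vax <- FALSE
  m <- mark_index_occasions(occ)
  expect_identical(m$is_index, c(FALSE, TRUE))

  # an early-vaccinated first occasion passes the index to the next one
  occ$early_vax <- c(FALSE, TRUE)
  m <- mark_index_occasions(occ)
  expect_identical(m$is_index, c(TRUE, FALSE))
})

test_that("index tie-breaking is deterministic and order-invariant", {
  occ <- rbind(
    mk_occ(occasion_id = "O2", child_id = "K2", due_date = 50L),
    mk_occ(occasion_id = "O1", child_id = "K1", due_date = 50L),
    mk_occ(occasion_id = "O3", child_id = "K1", due_date = 90L))
  occ$early_vax <- FALSE
  chosen <- sapply(1:20, function(i) {
    set.seed(i)
    perm <- occ[sample(nrow(occ)), ]
    m <- mark_index_occasions(perm)
    m$occasion_id[m$is_index]
  })
  expect_true(all(chosen == "O1"))  # earliest child_id wins the tie
})

test_that("exactly one index occasion per parent with any eligible occasion", {
  fx <- make_trial_occasions(n_parents = 600, seed = 3)
  occ <- fx$occasions
  per_parent <- tapply(occ$is_index, occ$parent_id, sum)
  any_elig <- tapply(!occ$early_vax, occ$parent_id, any)
  expect_true(all(per_parent[any_elig] == 1))
  expect_true(all(per_parent[!any_elig] == 0))
})
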