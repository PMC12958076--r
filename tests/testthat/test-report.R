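test_that("the printed-count fixture renders with its published totals", {
  counts <- table1_counts()
  tab <- arm_report_rows(counts)
  ctl <- tab[tab$framing == "control", ]
  expect_identical(ctl$index_n, 637L)
  expect_identical(ctl$ontime_n, 286L)
  expect_identical(ctl$ontime_prop, 0.45)   # 286/637 displays as 0.45
  expect_identical(c(ctl$bin_m14_0, ctl$bin_0_7, ctl$bin_7_28),
                   c(31L, 118L, 137L))
  tot <- tab[tab$timing == "Total", ]
  expect_identical(tot$index_n, 9933L)
  # bins partition the on-time receipts in every row
  expect_identical(tab$bin_m14_0 + tab$bin_0_7 + tab$bin_7_28,
                   tab$ontime_n)
  bad <- counts; bad$bin_0_7[2] <- bad$bin_0_7[2] + 1L
  expect_error(arm_report_rows(bad), "partition")
})

test_that("table_one aggregates occasion-level data consistently", {
  fx <- make_trial_occasions(n_parents = 800, or = 1.3, seed = 21)
  occ <- fx$occasions
  tab <- table_one(occ)
  expect_identical(nrow(tab), 14L)  # 13 arms + totals
  tot <- tab[tab$timing == "Total", ]
  expect_identical(tot$index_n,
                   sum(occ$is_index &
                         occ$status %in% c("ontime", "not_ontime")))
  expect_identical(tot$ontime_n, sum(occ$is_index &
                                       occ$status %in% "ontime"))
  # empty input: header-only with zero totals
  empty <- table_one(occ[0, ])
  expect_true(all(empty$index_n == 0L))
})

test_that("table_one rejects endpoints without an arm", {
  fx <- make_trial_occasions(n_parents = 200, seed = 22)
  occ <- fx$occasions
  occ$arm[which(occ$is_index)[1]] <- "mystery"
  expect_error(table_one(occ), "unknown arm")
})

test_that("exclusion percentages use integer display rounding", {
  # the published totals: 1366 of 22865 scheduled, 1310 at the 2-month point
  occ <- data.frame(
    schedule_point = rep(c(2L, 4L), c(4000, 18865)),
    status = "not_ontime", stringsAsFactors = FALSE)
  occ$status[1:1310] <- "excluded_early"
  occ$status[4001:4056] <- "excluded_early"
  s <- exclusion_summary(occ)
  expect_identical(s$n_total, 22865L)
  expect_identical(s$n_excluded, 1366L)
  expect_identical(s$pct_excluded, 6)
  two <- s$by_schedule_point
  expect_identical(two$pct_of_excluded[two$schedule_point == 2], 96)
  # zero exclusions
  s0 <- exclusion_summary(data.frame(schedule_point = 2L,
                                     status = "ontime"))
  expect_identical(s0$pct_excluded, 0)
  expect_identical(nrow(s0$by_schedule_point), 0L)
})

test_that("the five-model OR grid is laid out and formatted as printed", {
  fx <- make_trial_occasions(n_parents = 1200, or = 1.3, seed = 23)
  occ <- fx$occasions
  fits <- lapply(c(full = "full", shared = "shared",
                   timing_only = "timing_only"),
                 function(st)
                   summarise_arms(fit_posterior(build_design(
                     occ, model_spec(st, n_draws = 500, seed = 1)))))
  tab <- table_two(fits)
  # shared populates only the all-timings x all-framings cell
  shared_cells <- tab$shared[nzchar(tab$shared)]
  expect_identical(length(shared_cells), 1L)
  expect_identical(tab$shared[tab$timing == "all" & tab$framing == "all"],
                   shared_cells)
  # timing-only populates the three per-timing margins
  expect_identical(sum(nzchar(tab$timing_only)), 3L)
  # absent models leave explicit gaps
  expect_true(all(tab$no_interaction[tab$timing != "all" &
                                       tab$framing != "all"] == "-"))
  # cell format matches the printed style
  expect_true(all(grepl("^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}, \\d+\\.\\d{2}\\) \\d\\.\\d{2}$",
                        shared_cells)))
})

test_that("formatted cells match the printed precision convention", {
  expect_identical(adaptsms:::format_or_cell(1.29, 1.06, 1.55, 0.99),
                   "1.29 (1.06, 1.55) 0.99")
})

test_that("full-model cells cluster near a known generating OR", {
  fx <- make_trial_occasions(n_parents = 4000, or = 1.5, seed = 24)
  s <- summarise_arms(fit_posterior(build_design(
    fx$occasions, model_spec("full", n_draws = 1000, seed = 2))))
  expect_lt(abs(median(s$median_or) - 1.5), 0.25)
})

test_that("the occasion CSV round-trips exactly", {
  fx <- make_trial_occasions(n_parents = 300, seed = 25)
  occ <- fx$occasions
  path <- tempfile(fileext = ".csv")
  write_occasions_csv(occ, path)
  back <- read_occasions_csv(path)
  expect_identical(back$arm, occ$arm)
  for (col in c("occasion_id", "parent_id", "child_id", "clinic_id",
                "schedule_point", "due_date", "receipt_day", "epoch",
                "is_index", "status", "receipt_offset"))
    expect_identical(back[[col]], occ[[col]], label = col)
})

test_that("report generation is pure: identical input, identical bytes", {
  counts <- table1_counts()
  tab <- arm_report_rows(counts)
  p1 <- tempfile(fileext = ".md"); p2 <- tempfile(fileext = ".md")
  write_markdown_table(tab, p1)
  write_markdown_table(arm_report_rows(table1_counts()), p2)
  expect_identical(readLines(p1), readLines(p2))
  csv1 <- tempfile(); csv2 <- tempfile()
  write_occasions_csv(make_trial_occasions(100, seed = 9)$occasions, csv1)
  write_occasions_csv(make_trial_occasions(100, seed = 9)$occasions, csv2)
  expect_identical(readLines(csv1), readLines(csv2))
})

test_that("scenario configs round-trip through JSON and YAML", {
  cfg <- scenario_config(arm_log_or = arm_effects(1.5), seed = 3)
  pj <- tempfile(fileext = ".json")
  write_scenario(cfg, pj)
  cfg2 <- read_scenario(pj)
  expect_equal(cfg2$arm_log_or, cfg$arm_log_or)
  expect_equal(cfg2$baseline_ontime, cfg$baseline_ontime)
  py <- tempfile(fileext = ".yaml")
  write_scenario(cfg, py)
  expect_equal(read_scenario(py)$early_vax_prob, cfg$early_vax_prob)
})

test_that("arm summaries and adaptation logs are written out", {
  fx <- make_trial_occasions(n_parents = 400, seed = 26)
  s <- summarise_arms(fit_posterior(build_design(
    fx$occasions, model_spec("shared", n_draws = 300, seed = 4))))
  pc <- tempfile(fileext = ".csv")
  write_arm_summary(s, pc)
  expect_identical(nrow(utils::read.csv(pc)), 12L)
  pjson <- tempfile(fileext = ".json")
  write_arm_summary(s, pjson)
  expect_identical(length(jsonlite::read_json(pjson)), 12L)

  cfg <- scenario_config(arm_log_or = arm_effects(1.5),
                         n_parents_max = 2200, enrolment_per_day = 30)
  tr <- run_virtual_trial(cfg, seed = 6, n_draws = 300)
  pl <- tempfile(fileext = ".jsonl")
  append_adaptation_log(tr, pl)
  if (!is.null(tr$interims))
    expect_identical(length(readLines(pl)), nrow(tr$interims))
})
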