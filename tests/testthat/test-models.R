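test_that("design dimensions follow the factorial structure", {
  occ <- make_flat_occasions(3000, or = 1.2, seed = 2)
  arm_cols <- function(st) {
    d <- build_design(occ, model_spec(st))
    sum(grepl("^(framing|timing|ix|any_sms)", colnames(d$X)))
  }
  expect_identical(arm_cols("full"), 12L)          # 4 + 2 + 6
  expect_identical(arm_cols("no_interaction"), 6L) # 4 + 2
  expect_identical(arm_cols("framing_only"), 4L)
  expect_identical(arm_cols("timing_only"), 3L)
  expect_identical(arm_cols("shared"), 1L)

  d <- build_design(occ, model_spec("full"))
  # control reference: its arm-map row is all zero
  expect_true(all(d$arm_map["control", ] == 0))
  # every SMS arm's log-OR is a distinct coefficient combination
  expect_identical(nrow(unique(d$arm_map[-1, ])), 12L)
})

test_that("excluded and pending rows never enter the design", {
  occ <- make_flat_occasions(500, seed = 3)
  occ$status[1] <- "excluded_early"
  occ$status[2] <- NA
  d <- build_design(occ, model_spec("shared"))
  expect_identical(nrow(d$X), 498L)
  expect_error(build_design(occ[occ$status %in% "excluded_early", ],
                            model_spec("shared")), "no analysable")
})

test_that("index unit keeps one row per parent", {
  occ <- make_flat_occasions(200, seed = 4)
  occ$parent_id <- rep(sprintf("P%03d", 1:50), each = 4)
  occ$is_index <- rep(c(TRUE, FALSE, FALSE, FALSE), 50)
  d <- build_design(occ, model_spec("shared"))
  expect_identical(nrow(d$X), 50L)
  d_all <- build_design(occ, model_spec("shared", unit = "all_occasions"))
  expect_identical(nrow(d_all$X), 200L)
  expect_true(any(grepl("^parent:", colnames(d_all$X))))
})

test_that("sparse epochs are pooled with neighbours", {
  occ <- make_flat_occasions(400, seed = 5)
  occ$epoch <- c(rep(0L, 395), rep(1L, 2), rep(7L, 3))
  d <- build_design(occ, model_spec("shared", min_epoch_n = 10))
  expect_false(any(grepl("^epoch:", colnames(d$X))))  # all pooled into one
})

test_that("shared-model posterior matches the contingency-table log-OR", {
  # SMS 500/1000 on-time vs control 400/1000: sample log-OR = log(1.5)
  occ <- make_flat_occasions(2000, seed = 1)
  occ$arm <- rep(c("control", "neutral:day0"), each = 1000)
  occ$status <- c(rep(c("ontime", "not_ontime"), c(400, 600)),
                  rep(c("ontime", "not_ontime"), c(500, 500)))
  f <- fit_posterior(build_design(occ, model_spec("shared", n_draws = 10000,
                                                  seed = 9)))
  med <- median(f$draws[, "any_sms"])
  expect_lt(abs(med - log(1.5)), 0.05)
})

test_that("credible intervals match an independent percentile oracle", {
  occ <- make_flat_occasions(2000, or = 1.4, seed = 6)
  f <- fit_posterior(build_design(occ, model_spec("full", n_draws = 2000,
                                                  seed = 2)))
  s <- summarise_arms(f)
  lor <- f$draws %*% t(f$design$arm_map[-1, ])
  for (a in c(1L, 7L, 12L)) {
    srt <- sort(lor[, a])               # brute-force order statistics
    expect_equal(s$cri_low[a], exp(quantile(srt, 0.025, names = FALSE)))
    expect_equal(s$cri_high[a], exp(quantile(srt, 0.975, names = FALSE)))
    expect_equal(s$median_or[a], exp(median(srt)))
    expect_equal(s$pr_gt_1[a], mean(srt > 0))
    expect_equal(s$var_logodds[a], var(srt))
  }
  expect_true(all(s$cri_low <= s$median_or & s$median_or <= s$cri_high))
  expect_true(all(s$cri_low > 0))
})

test_that("Pr(best) is a probability distribution over active arms", {
  occ <- make_flat_occasions(4000, or = 1.3, seed = 7)
  f <- fit_posterior(build_design(occ, model_spec("full", n_draws = 1000,
                                                  seed = 3)))
  s <- summarise_arms(f)
  expect_equal(sum(s$pr_best), 1, tolerance = 1e-9)
  active <- sms_arms()[1:3]
  s3 <- summarise_arms(f, active_arms = active)
  expect_equal(sum(s3$pr_best), 1, tolerance = 1e-9)
  expect_true(all(s3$pr_best[!s3$arm %in% active] == 0))
})

test_that("degenerate and exchangeable draws give the expected Pr(best)", {
  occ <- make_flat_occasions(500, seed = 8)
  f <- fit_posterior(build_design(occ, model_spec("full", n_draws = 400,
                                                  seed = 4)))
  # arm 1 dominant in every draw
  f1 <- f
  f1$draws[] <- 0
  f1$draws[, "framing:neutral"] <- 1
  s <- summarise_arms(f1, active_arms = c("neutral:day-14", "risk:day0"))
  expect_equal(s$pr_best[s$arm == "neutral:day-14"], 1)
  expect_equal(s$pr_best[s$arm == "risk:day0"], 0)
  # exchangeable ties split evenly
  f2 <- f
  f2$draws[] <- 0
  s2 <- summarise_arms(f2)
  expect_equal(s2$pr_best, rep(1 / 12, 12))
})

test_that("a shared pooled model recovers its generating effect", {
  occ <- make_flat_occasions(50000, or = 1.29, p0 = 0.45, seed = 10)
  f <- fit_posterior(build_design(occ, model_spec("shared", n_draws = 4000,
                                                  seed = 5)))
  md <- marginal_difference(f, arms = "neutral:day0")
  # closed form: p1 = 1.29 * odds0 / (1 + 1.29 * odds0), odds0 = 0.45/0.55
  p1 <- 1.29 * (0.45 / 0.55) / (1 + 1.29 * (0.45 / 0.55))
  expect_lt(abs(md$median - (p1 - 0.45)), 0.02)
})

test_that("marginal differences follow the closed inverse-logit form", {
  occ <- make_flat_occasions(500, seed = 11)
  f <- fit_posterior(build_design(occ, model_spec("shared", n_draws = 200,
                                                  seed = 6)))
  # freeze draws at exact values: intercept logit(0.45), shared log(1.29)
  f0 <- constant_draw_fit(f, list("(Intercept)" = qlogis(0.45),
                                  "any_sms" = log(1.29)))
  md <- marginal_difference(f0, arms = "positive:day+7")
  p1 <- 1.29 * (0.45 / 0.55) / (1 + 1.29 * (0.45 / 0.55))
  expect_equal(md$median, p1 - 0.45, tolerance = 1e-10)
  expect_equal(md$cri_low, md$cri_high)  # degenerate draws, zero width
  # all-null draws give exactly zero difference
  f00 <- constant_draw_fit(f, list("(Intercept)" = qlogis(0.45)))
  md0 <- marginal_difference(f00, arms = "positive:day+7")
  expect_identical(md0$median, 0)
})

test_that("posterior calibration is honest under the null", {
  # over replicates the pooled Pr(OR>1) must be uniform-ish (mean ~0.5)
  # and the median OR centred at 1
  prs <- meds <- numeric(30)
  for (i in 1:30) {
    occ <- make_flat_occasions(5000, or = 1, seed = 100 + i)
    f <- fit_posterior(build_design(occ, model_spec("shared", n_draws = 500,
                                                    seed = i)))
    prs[i] <- mean(f$draws[, "any_sms"] > 0)
    meds[i] <- median(f$draws[, "any_sms"])
  }
  expect_lt(abs(mean(prs) - 0.5), 0.15)
  expect_lt(abs(mean(meds)), 0.05)
  expect_true(all(exp(meds) > 0.8 & exp(meds) < 1.25))
})

test_that("interaction posteriors vanish when data have none", {
  # framing x timing effects multiply (log-additive), no interaction
  fr_or <- c(neutral = 1.1, positive = 1.3, risk = 1.2, social = 1.4)
  tm_or <- c("day-14" = 1.0, "day0" = 1.1, "day+7" = 0.95)
  at <- arm_table()[-1, ]
  ors <- fr_or[as.character(at$framing)] * tm_or[as.character(at$timing)]
  occ <- make_flat_occasions(100000, or = setNames(ors, at$arm), seed = 12)
  f <- fit_posterior(build_design(occ, model_spec("full", n_draws = 2000,
                                                  seed = 7)))
  ix <- grep("^ix:", colnames(f$draws), value = TRUE)
  expect_identical(length(ix), 6L)
  expect_true(all(abs(apply(f$draws[, ix], 2, median)) < 0.1))
})

test_that("separation is caught by the priors with a warning", {
  occ <- make_flat_occasions(400, seed = 13)
  occ$status[occ$arm == "social:day+7"] <- "ontime"
  d <- build_design(occ, model_spec("full", n_draws = 100, seed = 8))
  expect_warning(fit_posterior(d), "separat")
})

test_that("posterior draws are reproducible under a fixed seed", {
  occ <- make_flat_occasions(800, seed = 14)
  d <- build_design(occ, model_spec("shared", n_draws = 300, seed = 21))
  f1 <- fit_posterior(d)
  f2 <- fit_posterior(d)
  expect_identical(f1$draws, f2$draws)
})
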