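#' Run one virtual adaptive trial
#'
#' Simulates the whole design end to end: enrolment of families, daily
#' screening, mass-weighted-urn randomisation of each parent at their first
#' SMS-eligible occasion, outcome generation under the scenario's logistic
#' model, interim analyses once 1500 (then every further 500) index
#' occasions complete follow-up, response-adaptive retargeting of the
#' reminder arms, the control-discontinuation superiority rule, and a final
#' analysis on all completed data. Interim fits use only occasions whose
#' 28-day follow-up is complete at the (simulated) trigger date; control
#' outcomes stay in every analysis dataset after the arm is dropped — only
#' future allocation stops.
#'
#' Everything is deterministic given `(config, thresholds, seed)`.
#'
#' @param config An [scenario_config()].
#' @param thresholds A [decision_thresholds()].
#' @param seed Integer seed.
#' @param engine,n_draws Posterior engine and draw count used at interim and
#'   final analyses (defaults `"laplace"` and 2000, the replicate-simulation
#'   settings; one-shot analyses typically use 10000 draws).
#' @param adapt Apply response-adaptive retargeting at interims.
#' @param drop_control Apply the control-discontinuation rule (disabled
#'   inside [calibrate_threshold()], where the interim statistics are
#'   collected without acting on them).
#' @param alpha_urn Urn mass parameter for the randomisation.
#' @param first_interim,interim_step Interim trigger schedule.
#' @param weight_form Passed to [compute_rar_targets()].
#' @param keep_data Return the occasion-level analysis data.
#' @return An object of class `sms_trial`: counts per arm (`n`, `ontime`),
#'   an `interims` data frame (analysis index, day, completed n, pooled and
#'   max-arm posterior probabilities, declaration and control flags), the
#'   final analysis summaries, `declared_effective`, `max_stat` (largest
#'   superiority statistic over all analyses), `n_randomised`, `seed`.
#' @export
run_virtual_trial <- function(config,
                              thresholds = decision_thresholds(),
                              seed = NULL,
                              engine = "laplace",
                              n_draws = 2000L,
                              adapt = TRUE,
                              drop_control = TRUE,
                              alpha_urn = 4,
                              first_interim = 1500L,
                              interim_step = 500L,
                              weight_form = "sqrt_product",
                              keep_data = FALSE) {
  stopifnot(inherits(config, "sms_scenario"),
            inherits(thresholds, "decision_thresholds"))
  if (!is.null(seed)) set.seed(seed)
  pop <- generate_population(config, seed = NULL)
  occ <- pop$occasions
  arms <- arm_table()$arm

  empty_result <- function() {
    structure(list(config = config, thresholds = thresholds, seed = seed,
                   n_randomised = 0L,
                   arm_counts = data.frame(arm = arms, n = 0L, ontime = 0L),
                   interims = NULL, final = NULL,
                   declared_effective = FALSE, max_stat = NA_real_,
                   data = NULL),
              class = "sms_trial")
  }
  if (nrow(occ) == 0L) return(empty_result())

  # parent screening flags; index occasion per parent (arm-independent:
  # early vaccination precedes any reminder)
  par <- pop$parents
  ok_parent <- !par$opted_out & par$has_phone & par$has_name_dob
  elig <- !occ$early_vax & ok_parent[match(occ$parent_id, par$parent_id)]
  occ <- mark_index_occasions(occ, eligible = elig)
  idx <- occ[occ$is_index, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty_result())

  pm <- match(idx$parent_id, par$parent_id)
  u <- pop$clinics$random_effect[match(idx$clinic_id, pop$clinics$clinic_id)]
  v <- par$random_effect[pm]
  dat <- data.frame(
    parent_id = idx$parent_id,
    clinic_id = idx$clinic_id,
    schedule_point = idx$schedule_point,
    due_date = idx$due_date,
    epoch = idx$epoch,
    rand_day = pmax(par$enrol_day[pm], idx$due_date - 28L),
    completion = idx$due_date + 28L,
    p_lin = stats::qlogis(
      config$baseline_ontime[as.character(idx$schedule_point)]) +
      u + v + config$epoch_drift * idx$epoch,
    arm = NA_character_,
    status = NA_character_,
    is_index = TRUE,
    stringsAsFactors = FALSE
  )
  dat <- dat[order(dat$rand_day, dat$parent_id), , drop = FALSE]
  n_par <- nrow(dat)

  # interim calendar: day on which the k-th trigger count completes
  comp_sorted <- sort(dat$completion)
  trigger_n <- if (first_interim > n_par) integer(0) else
    seq(first_interim, n_par, by = interim_step)
  interim_days <- comp_sorted[trigger_n]
  keep_i <- !duplicated(interim_days)
  interim_days <- interim_days[keep_i]

  st <- init_allocation(initial_targets(), alpha_urn = alpha_urn)
  assigned_upto <- 0L
  control_active <- TRUE
  declared <- FALSE
  warm <- list(full = NULL, shared = NULL)
  interims <- list()
  spec_full <- model_spec("full", engine = engine, n_draws = n_draws)
  spec_shared <- model_spec("shared", engine = engine, n_draws = n_draws)

  assign_through <- function(day) {
    todo <- which(seq_len(n_par) > assigned_upto & dat$rand_day <= day)
    if (length(todo)) {
      dat$arm[todo] <<- assign_arms(st, dat$parent_id[todo])
      p <- stats::plogis(dat$p_lin[todo] + config$arm_log_or[dat$arm[todo]])
      dat$status[todo] <<- ifelse(stats::runif(length(todo)) < p,
                                  "ontime", "not_ontime")
      assigned_upto <<- max(todo)
    }
  }

  fit_frozen <- function(day, spec, warm_start) {
    rows <- dat$completion <= day & !is.na(dat$arm)
    des <- build_design(dat[rows, , drop = FALSE], spec)
    start <- NULL
    if (!is.null(warm_start)) {
      start <- stats::setNames(numeric(ncol(des$X)), colnames(des$X))
      common <- intersect(names(warm_start), names(start))
      start[common] <- warm_start[common]
    }
    fit_posterior(des, spec, start = start)
  }

  analyse <- function(day, analysis_index, n_complete, is_final = FALSE) {
    fit_full <- fit_frozen(day, spec_full, warm$full)
    fit_shared <- fit_frozen(day, spec_shared, warm$shared)
    warm$full <<- fit_full$mode
    warm$shared <<- fit_shared$mode
    active <- names(which(st$active))
    active_sms <- setdiff(active, "control")
    summ <- summarise_arms(fit_full, active_arms = active_sms)
    # exact normal tails under the Laplace engine: no draw granularity in
    # the stopping statistics
    shared_contrast <- stats::setNames(numeric(ncol(fit_shared$design$X)),
                                       colnames(fit_shared$design$X))
    shared_contrast["any_sms"] <- 1
    pooled <- pr_positive(fit_shared, shared_contrast)
    arm_pr <- pr_positive(fit_full, fit_full$design$arm_map[-1L, ,
                                                           drop = FALSE])
    max_arm <- max(arm_pr)
    stat <- max(pooled, max_arm)
    hit <- stat >= thresholds$superiority_prob
    list(day = day, analysis_index = analysis_index,
         n_complete = n_complete, pooled_pr = pooled,
         max_arm_pr = max_arm, stat = stat, hit = hit,
         summary = summ, fit_full = fit_full, fit_shared = fit_shared)
  }

  for (k in seq_along(interim_days)) {
    day <- interim_days[k]
    assign_through(day)
    n_complete <- sum(dat$completion <= day & !is.na(dat$arm))
    an <- analyse(day, k, n_complete)
    if (an$hit) declared <- TRUE
    if (drop_control && declared && control_active) {
      control_active <- FALSE
    }
    if (adapt) {
      tg <- compute_rar_targets(an$summary, control_active = control_active,
                                weight_form = weight_form)
      deact <- if (!control_active && st$active[["control"]]) "control"
      retarget(st, tg, deactivate = deact)
    }
    interims[[k]] <- data.frame(
      analysis_index = k, day = day, n_complete = n_complete,
      pooled_pr = an$pooled_pr, max_arm_pr = an$max_arm_pr,
      declared = declared, control_active = control_active)
  }

  # finish assigning everyone and run the final analysis on all completed
  assign_through(Inf)
  final_day <- max(dat$completion)
  n_complete <- sum(!is.na(dat$arm))
  final <- NULL
  stats_all <- vapply(interims, function(x) max(x$pooled_pr, x$max_arm_pr),
                      numeric(1))
  if (n_complete >= 25L) {
    fin <- analyse(final_day, length(interims) + 1L, n_complete,
                   is_final = TRUE)
    if (fin$hit) declared <- TRUE
    stats_all <- c(stats_all, fin$stat)
    final <- list(day = final_day, n_complete = n_complete,
                  pooled_pr = fin$pooled_pr, max_arm_pr = fin$max_arm_pr,
                  arm_summary = fin$summary,
                  pooled_summary = summarise_arms(fin$fit_shared)[1L,
                    c("median_or", "cri_low", "cri_high", "pr_gt_1")])
  }

  counts <- data.frame(arm = arms,
                       n = as.integer(table(factor(dat$arm, arms))),
                       ontime = as.integer(table(factor(
                         dat$arm[dat$status %in% "ontime"], arms))))
  structure(list(config = config, thresholds = thresholds, seed = seed,
                 n_randomised = sum(!is.na(dat$arm)),
                 arm_counts = counts,
                 interims = if (length(interims))
                   do.call(rbind, interims) else NULL,
                 final = final,
                 declared_effective = declared,
                 max_stat = if (length(stats_all)) max(stats_all)
                 else NA_real_,
                 data = if (keep_data) dat else NULL),
            class = "sms_trial")
}

#' @export
print.sms_trial <- function(x, ...) {
  cat(sprintf("Virtual adaptive trial: %d parents randomised, %d interim analyses\n",
              x$n_randomised,
              if (is.null(x$interims)) 0L else nrow(x$interims)))
  cat(sprintf("  effectiveness declared: %s", x$declared_effective))
  if (!is.null(x$interims) && any(x$interims$declared))
    cat(sprintf(" (first at interim %d)",
                min(x$interims$analysis_index[x$interims$declared])))
  cat("\n")
  if (!is.null(x$final))
    cat(sprintf("  final pooled OR %.2f (%.2f, %.2f), Pr(>1) = %.3f\n",
                x$final$pooled_summary$median_or,
                x$final$pooled_summary$cri_low,
                x$final$pooled_summary$cri_high,
                x$final$pooled_summary$pr_gt_1))
  invisible(x)
}

#' Operating characteristics over replicate trials
#'
#' Runs independently seeded replicates of [run_virtual_trial()] and
#' aggregates the frequentist design properties: the declare rate (the
#' fraction of replicates in which the superiority declaration fires at any
#' interim or the final analysis — the power under an effective scenario,
#' the type I assertion probability under the null), with its Monte Carlo
#' standard error, plus mean per-arm allocation.
#'
#' @param config,thresholds,... Passed to [run_virtual_trial()].
#' @param n_replicates Number of replicate trials.
#' @param base_seed Seed for the replicate seed stream.
#' @return An object of class `sms_oc`.
#' @export
estimate_oc <- function(config, thresholds = decision_thresholds(),
                        n_replicates = 200L, base_seed = 1L, ...) {
  stopifnot(n_replicates >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  res <- lapply(seeds, function(s)
    run_virtual_trial(config, thresholds, seed = s, ...))
  declared <- vapply(res, `[[`, logical(1), "declared_effective")
  nrand <- vapply(res, `[[`, integer(1), "n_randomised")
  alloc <- vapply(res, function(r) {
    n <- r$arm_counts$n
    if (sum(n) == 0) rep(0, length(n)) else n / sum(n)
  }, numeric(13L))
  rate <- mean(declared)
  structure(list(
    n_replicates = n_replicates,
    declare_rate = rate,
    mcse = sqrt(rate * (1 - rate) / n_replicates),
    mean_total_n = mean(nrand),
    mean_allocation = stats::setNames(rowMeans(alloc),
                                      arm_table()$arm),
    threshold = thresholds$superiority_prob,
    max_stats = vapply(res, `[[`, numeric(1), "max_stat"),
    base_seed = base_seed
  ), class = "sms_oc")
}

#' @export
print.sms_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d replicate trials (threshold %g)\n",
              x$n_replicates, x$threshold))
  cat(sprintf("  declare rate: %.3f (MCSE %.3f) | mean randomised: %.0f\n",
              x$declare_rate, x$mcse, x$mean_total_n))
  cat(sprintf("  mean allocation: control %.3f, reminder arms %.3f-%.3f\n",
              x$mean_allocation[["control"]],
              min(x$mean_allocation[-1L]), max(x$mean_allocation[-1L])))
  invisible(x)
}

#' Calibrate the superiority threshold under the null
#'
#' Simulates replicate trials under a global-null scenario with the
#' control-discontinuation rule disabled, records each replicate's largest
#' superiority statistic (max over analyses of the pooled and best
#' single-arm posterior probabilities), and evaluates the declare rate at
#' every candidate threshold from that one set of replicates. This is
#' exact, not a shortcut: under the null a declaration only affects future
#' allocation, and the declared flag is absorbing, so a trial declares at
#' threshold t precisely when its no-drop statistic trajectory ever
#' reaches t. Returns the smallest grid threshold whose estimated type I
#' assertion probability is at most `alpha`.
#'
#' @param config_null A null scenario (all arm odds ratios 1).
#' @param grid Increasing candidate thresholds in (0.5, 1).
#' @param n_replicates Replicates used for calibration.
#' @param base_seed Seed for the replicate stream.
#' @param alpha Target type I assertion probability (default 0.05).
#' @param ... Passed to [run_virtual_trial()].
#' @return An object of class `sms_calibration`: `threshold` (`NA` if no
#'   grid point controls type I; check `achieved`), `grid`, `rates`
#'   (nonincreasing along the grid), `achieved`, `n_replicates`.
#' @export
calibrate_threshold <- function(config_null,
                                grid = c(0.99, 0.995, 0.999, 0.9995,
                                         0.9999, 0.99995, 0.99999),
                                n_replicates = 100L, base_seed = 1L,
                                alpha = 0.05, ...) {
  stopifnot(all(diff(grid) > 0), all(grid > 0.5 & grid < 1))
  oc <- estimate_oc(config_null, decision_thresholds(min(grid)),
                    n_replicates = n_replicates, base_seed = base_seed,
                    drop_control = FALSE, ...)
  ms <- oc$max_stats
  rates <- vapply(grid, function(t) mean(ms >= t, na.rm = TRUE), numeric(1))
  if (any(diff(rates) > 0))
    stop("internal error: declare rate not monotone in threshold")
  ok <- rates <= alpha
  structure(list(
    threshold = if (any(ok)) grid[which(ok)[1L]] else NA_real_,
    achieved = any(ok),
    grid = grid, rates = rates, alpha = alpha,
    n_replicates = n_replicates, base_seed = base_seed
  ), class = "sms_calibration")
}

#' @export
print.sms_calibration <- function(x, ...) {
  cat(sprintf("Threshold calibration on %d null replicates (target %.2f)\n",
              x$n_replicates, x$alpha))
  print(data.frame(threshold = x$grid, declare_rate = x$rates),
        row.names = FALSE)
  if (x$achieved)
    cat(sprintf("  selected threshold: %g\n", x$threshold))
  else cat("  no grid threshold controls the type I assertion probability\n")
  invisible(x)
}
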