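#' Scenario configuration for a virtual trial
#'
#' Bundles every quantity the synthetic generator and trial engine need: the
#' enrolment process, family structure, clinic and parent random effects,
#' per-schedule-point baseline on-time probabilities, per-arm effects, early
#' vaccination, calendar drift, and receipt-day detail. The defaults encode
#' the design-evaluation scenario: a 0.45 baseline on-time probability at
#' every schedule point, a 10,000-parent cap, 20 clinics, and family sizes
#' 86/13/1% for one/two/three children.
#'
#' @param n_parents_max Cap on randomised parents (default 10000).
#' @param n_clinics Number of participating clinics (default 20).
#' @param family_size_probs Probability vector over 1-4 children per parent.
#' @param baseline_ontime Probability of on-time vaccination at each schedule
#'   point for a control parent at a typical clinic in epoch 0; scalar or
#'   named vector over `schedule_points()`.
#' @param arm_log_or Named length-13 vector of log odds ratios versus control
#'   (control entry must be 0); see [arm_effects()].
#' @param sigma_clinic SD of the clinic random effect on the log-odds scale.
#' @param sigma_parent SD of the parent random effect (used by all-occasion
#'   secondary models).
#' @param epoch_drift Additive log-odds change per 4-week calendar epoch.
#' @param early_vax_prob Probability that an occasion is vaccinated more than
#'   14 days before its due date (and is therefore SMS-ineligible); scalar or
#'   named vector over schedule points.
#' @param enrolment_per_day Mean number of new parents screened in per day.
#' @param horizon_days Trial duration in days from first enrolment.
#' @param p_newborn Probability a family enters with a newborn (<2 months);
#'   otherwise the eldest child's age at enrolment is uniform on 2-46 months.
#' @param ontime_bin_probs Probabilities that an on-time receipt falls in the
#'   day bins (-14,0], (0,7], (7,28]; default is the control row of the
#'   printed timing breakdown, 31/118/137 of 286.
#' @param late_receipt_prob Probability that a not-on-time occasion has any
#'   receipt record (late, beyond day 28) rather than none.
#' @param late_mean_extra_days Mean extra delay beyond day 28 for late
#'   receipts (geometric).
#' @param opt_out_prob Probability a parent has opted out of SMS contact.
#' @param missing_phone_prob,missing_name_dob_prob Probabilities of the
#'   corresponding screening exclusions.
#' @param seed Optional integer seed stored with the scenario.
#' @return An object of class `sms_scenario` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(arm_log_or = arm_effects(1.5), n_parents_max = 2000)
#' cfg
scenario_config <- function(n_parents_max = 10000L,
                            n_clinics = 20L,
                            family_size_probs = c(0.86, 0.13, 0.01, 0.00),
                            baseline_ontime = 0.45,
                            arm_log_or = arm_effects(1),
                            sigma_clinic = 0.15,
                            sigma_parent = 0.25,
                            epoch_drift = -0.01,
                            early_vax_prob = c("2" = 0.32, "4" = 0.003,
                                               "6" = 0.003, "12" = 0.003,
                                               "18" = 0.003, "48" = 0.003),
                            enrolment_per_day = 40,
                            horizon_days = 420L,
                            p_newborn = 0.5,
                            ontime_bin_probs = c(31, 118, 137) / 286,
                            late_receipt_prob = 0.5,
                            late_mean_extra_days = 30,
                            opt_out_prob = 0,
                            missing_phone_prob = 0,
                            missing_name_dob_prob = 0,
                            seed = NULL) {
  pts <- schedule_points()
  expand_pt <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(pts)), pts)
    if (is.null(names(x)) && length(x) == length(pts)) names(x) <- pts
    if (!setequal(names(x), as.character(pts)))
      stop(what, " must be named by schedule points ",
           paste(pts, collapse = ", "), call. = FALSE)
    x[as.character(pts)]
  }
  baseline_ontime <- expand_pt(baseline_ontime, "baseline_ontime")
  early_vax_prob <- expand_pt(early_vax_prob, "early_vax_prob")

  check_probvec <- function(x, what) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
      stop(what, " must be nonnegative and sum to 1", call. = FALSE)
  }
  check_probvec(family_size_probs, "family_size_probs")
  check_probvec(ontime_bin_probs, "ontime_bin_probs")
  stopifnot(length(family_size_probs) == 4L)
  if (any(baseline_ontime <= 0 | baseline_ontime >= 1))
    stop("baseline_ontime must lie strictly in (0, 1)", call. = FALSE)
  if (any(early_vax_prob < 0 | early_vax_prob > 1))
    stop("early_vax_prob must lie in [0, 1]", call. = FALSE)
  arms <- arm_table()$arm
  if (!identical(names(arm_log_or), arms) || arm_log_or[["control"]] != 0)
    stop("arm_log_or must be named by the 13 arms with control = 0; ",
         "use arm_effects()", call. = FALSE)
  if (n_clinics < 1L) stop("n_clinics must be >= 1", call. = FALSE)
  if (horizon_days < 28L) stop("horizon_days must be >= 28", call. = FALSE)
  stopifnot(sigma_clinic >= 0, sigma_parent >= 0, enrolment_per_day >= 0,
            n_parents_max >= 0, p_newborn >= 0, p_newborn <= 1,
            late_receipt_prob >= 0, late_receipt_prob <= 1,
            late_mean_extra_days > 0,
            opt_out_prob >= 0, opt_out_prob <= 1,
            missing_phone_prob >= 0, missing_phone_prob <= 1,
            missing_name_dob_prob >= 0, missing_name_dob_prob <= 1)

  structure(list(
    n_parents_max = as.integer(n_parents_max),
    n_clinics = as.integer(n_clinics),
    family_size_probs = family_size_probs,
    baseline_ontime = baseline_ontime,
    arm_log_or = arm_log_or,
    sigma_clinic = sigma_clinic,
    sigma_parent = sigma_parent,
    epoch_drift = epoch_drift,
    early_vax_prob = early_vax_prob,
    enrolment_per_day = enrolment_per_day,
    horizon_days = as.integer(horizon_days),
    p_newborn = p_newborn,
    ontime_bin_probs = ontime_bin_probs,
    late_receipt_prob = late_receipt_prob,
    late_mean_extra_days = late_mean_extra_days,
    opt_out_prob = opt_out_prob,
    missing_phone_prob = missing_phone_prob,
    missing_name_dob_prob = missing_name_dob_prob,
    seed = seed
  ), class = "sms_scenario")
}

#' Routine vaccination schedule points
#'
#' Child ages, in months, at which scheduled doses fall due.
#'
#' @return Integer vector `c(2, 4, 6, 12, 18, 48)`.
#' @export
schedule_points <- function() c(2L, 4L, 6L, 12L, 18L, 48L)

#' @rdname schedule_points
#' @return `schedule_point_days()`: due day of each schedule point relative
#'   to birth (months converted at 365.25/12 days).
#' @export
schedule_point_days <- function() {
  stats::setNames(as.integer(round(schedule_points() * 365.25 / 12)),
                  schedule_points())
}

#' @export
print.sms_scenario <- function(x, ...) {
  ors <- exp(x$arm_log_or[-1L])
  cat("Trial scenario:\n")
  cat(sprintf("  parents (cap) %d | clinics %d | enrolment %.1f/day | horizon %d days\n",
              x$n_parents_max, x$n_clinics, x$enrolment_per_day,
              x$horizon_days))
  cat(sprintf("  baseline on-time: %s\n",
              paste(sprintf("%gm=%.2f", schedule_points(), x$baseline_ontime),
                    collapse = " ")))
  if (max(ors) - min(ors) < 1e-12) {
    cat(sprintf("  reminder arms: all at OR %.3g vs control\n", ors[[1L]]))
  } else {
    cat(sprintf("  reminder arm ORs vs control: %.2f-%.2f\n",
                min(ors), max(ors)))
  }
  cat(sprintf("  sigma_clinic %.3g | sigma_parent %.3g | epoch drift %+.3g\n",
              x$sigma_clinic, x$sigma_parent, x$epoch_drift))
  invisible(x)
}

#' Read or write a scenario as YAML/JSON
#'
#' @param config An `sms_scenario`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scenario()` returns an `sms_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "sms_scenario"))
  x <- unclass(config)
  # named vectors must become objects/maps, not bare arrays
  x <- lapply(x, function(v)
    if (!is.null(names(v)) && length(v) > 1L) as.list(v) else v)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output", call. = FALSE)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$arm_log_or <- unlist(x$arm_log_or)
  for (nm in c("family_size_probs", "baseline_ontime", "early_vax_prob",
               "ontime_bin_probs"))
    x[[nm]] <- unlist(x[[nm]])
  do.call(scenario_config, x)
}
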