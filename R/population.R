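#' Generate a synthetic trial population
#'
#' Builds clinics (with log-odds random effects), families of 1-4 children
#' attached to clinics, and every scheduled vaccine occasion falling inside
#' the trial horizon. Enrolment is a homogeneous daily Poisson process capped
#' at `n_parents_max`; a family enters when one of its children approaches a
#' scheduled dose, so each family's first due date lies at or after its
#' enrolment day. Occasions are flagged `early_vax` when the dose will be
#' given more than 14 days before its due date (these are SMS-ineligible);
#' the flag is drawn here, independently of any arm, because in the trial
#' early vaccination precedes any reminder.
#'
#' @param config An [scenario_config()] object.
#' @param seed Optional integer seed; defaults to `config$seed`. When `NULL`,
#'   the current RNG state is used.
#' @return An object of class `sms_population`: a list with data frames
#'   `clinics` (`clinic_id`, `random_effect`, `size_weight`), `parents`
#'   (`parent_id`, `clinic_id`, `random_effect`, `n_children`, `enrol_day`,
#'   `opted_out`, `has_phone`, `has_name_dob`), `children` (`child_id`,
#'   `parent_id`, `birth_day`) and `occasions` (`occasion_id`, `parent_id`,
#'   `child_id`, `clinic_id`, `schedule_point`, `due_date`, `epoch`,
#'   `early_vax`), plus the `config`. Day 0 is the first enrolment day;
#'   `epoch = floor(due_date / 28)`.
#' @export
#' @examples
#' pop <- generate_population(scenario_config(n_parents_max = 200, seed = 1))
#' pop
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sms_scenario"))
  if (!is.null(seed)) set.seed(seed)

  clinics <- data.frame(
    clinic_id = sprintf("C%02d", seq_len(config$n_clinics)),
    random_effect = stats::rnorm(config$n_clinics, 0, config$sigma_clinic),
    size_weight = stats::rgamma(config$n_clinics, shape = 4, rate = 4),
    stringsAsFactors = FALSE
  )

  # enrolment stops 56 days before the horizon so first occasions can both
  # fall due (within 28 days) and complete their 28-day follow-up inside it
  enrol_window <- max(0L, config$horizon_days - 56L)
  arrivals <- stats::rpois(enrol_window + 1L, config$enrolment_per_day)
  n_parents <- min(sum(arrivals), config$n_parents_max)
  empty <- n_parents == 0L
  if (empty && config$n_parents_max > 0L && config$enrolment_per_day > 0)
    warning("horizon too short for any enrolment; population is empty")
  enrol_day <- rep.int(seq_along(arrivals) - 1L, arrivals)[seq_len(n_parents)]

  parents <- data.frame(
    parent_id = sprintf("P%05d", seq_len(n_parents)),
    clinic_id = if (empty) character(0) else
      sample(clinics$clinic_id, n_parents, replace = TRUE,
             prob = clinics$size_weight),
    random_effect = stats::rnorm(n_parents, 0, config$sigma_parent),
    n_children = if (empty) integer(0) else
      sample(1:4, n_parents, replace = TRUE, prob = config$family_size_probs),
    enrol_day = enrol_day,
    opted_out = stats::runif(n_parents) < config$opt_out_prob,
    has_phone = stats::runif(n_parents) >= config$missing_phone_prob,
    has_name_dob = stats::runif(n_parents) >= config$missing_name_dob_prob,
    stringsAsFactors = FALSE
  )

  # eldest child: newborn with prob p_newborn, else 2-46 months old at entry;
  # siblings are successively 1-3 years older
  n_child <- sum(parents$n_children)
  child_parent <- rep.int(seq_len(n_parents), parents$n_children)
  birth_order <- sequence(parents$n_children)
  eldest_age <- ifelse(stats::runif(n_parents) < config$p_newborn,
                       sample(0:60, max(n_parents, 1L), replace = TRUE),
                       sample(61:1399, max(n_parents, 1L), replace = TRUE)
                       )[seq_len(n_parents)]
  extra_gap <- sample(366:1095, max(n_child, 1L),
                      replace = TRUE)[seq_len(n_child)]
  age_at_enrol <- eldest_age[child_parent] +
    ifelse(birth_order > 1L, extra_gap, 0L) * (birth_order > 1L)
  # cumulative gaps for 3rd/4th children
  if (any(birth_order > 2L)) {
    for (k in 3:4) {
      idx <- which(birth_order == k)
      if (length(idx))
        age_at_enrol[idx] <- age_at_enrol[idx - 1L] + extra_gap[idx]
    }
  }
  children <- data.frame(
    child_id = sprintf("K%05d", seq_len(n_child)),
    parent_id = parents$parent_id[child_parent],
    birth_day = parents$enrol_day[child_parent] - age_at_enrol,
    stringsAsFactors = FALSE
  )

  # expand children x schedule points, keep occasions due in
  # [enrol_day, horizon]
  pts <- schedule_points()
  pt_day <- schedule_point_days()
  nrep <- length(pts)
  occ <- data.frame(
    parent_id = rep(children$parent_id, each = nrep),
    child_id = rep(children$child_id, each = nrep),
    schedule_point = rep(pts, times = n_child),
    due_date = rep(children$birth_day, each = nrep) +
      rep(unname(pt_day), times = n_child),
    stringsAsFactors = FALSE
  )
  keep <- occ$due_date >= rep(parents$enrol_day[child_parent], each = nrep) &
    occ$due_date <= config$horizon_days
  occ <- occ[keep, , drop = FALSE]
  if (nrow(occ)) {
    occ <- occ[order(occ$parent_id, occ$child_id, occ$due_date), ,
               drop = FALSE]
  }
  occ$occasion_id <- sprintf("O%06d", seq_len(nrow(occ)))
  occ$clinic_id <- parents$clinic_id[match(occ$parent_id, parents$parent_id)]
  occ$epoch <- occ$due_date %/% 28L
  occ$early_vax <- stats::runif(nrow(occ)) <
    config$early_vax_prob[as.character(occ$schedule_point)]
  rownames(occ) <- NULL
  occ <- occ[, c("occasion_id", "parent_id", "child_id", "clinic_id",
                 "schedule_point", "due_date", "epoch", "early_vax")]

  structure(list(clinics = clinics, parents = parents, children = children,
                 occasions = occ, config = config),
            class = "sms_population")
}

#' @export
print.sms_population <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial population: %d parents, %d children, %d occasions, %d clinics\n",
    nrow(x$parents), nrow(x$children), nrow(x$occasions), nrow(x$clinics)))
  if (nrow(x$occasions))
    cat(sprintf("  due dates span day %d-%d (%d epochs)\n",
                min(x$occasions$due_date), max(x$occasions$due_date),
                length(unique(x$occasions$epoch))))
  invisible(x)
}

#' On-time probability implied by the outcome model
#'
#' Closed-form inverse-logit of the generator's linear predictor:
#' `plogis(qlogis(baseline) + arm effect + clinic + parent + drift * epoch)`.
#'
#' @param config An [scenario_config()].
#' @param schedule_point Schedule point(s) in months.
#' @param arm Arm label(s) (see [arm_table()]).
#' @param clinic_effect,parent_effect Log-odds random effects (default 0).
#' @param epoch 4-week epoch index (default 0).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' cfg <- scenario_config(arm_log_or = arm_effects(1.5))
#' ontime_probability(cfg, 4, "neutral:day0")  # 0.45 odds x 1.5 -> 0.551
ontime_probability <- function(config, schedule_point, arm,
                               clinic_effect = 0, parent_effect = 0,
                               epoch = 0) {
  base <- config$baseline_ontime[as.character(schedule_point)]
  if (anyNA(base)) stop("unknown schedule point", call. = FALSE)
  eff <- config$arm_log_or[arm]
  if (anyNA(eff)) stop("unknown arm label", call. = FALSE)
  stats::plogis(stats::qlogis(base) + eff + clinic_effect + parent_effect +
                  config$epoch_drift * epoch)
}

#' Simulate vaccination receipt days
#'
#' Draws a receipt day offset (relative to the due date) for each occasion
#' given its assigned arm. Early-vaccinated occasions (drawn here with
#' probability `early_vax_prob` per schedule point unless the occasions
#' already carry an `early_vax` flag) receive the dose 15-45 days before the
#' due date. Otherwise an on-time indicator is drawn from the logistic model
#' (baseline log-odds + arm effect + clinic and parent effects + calendar
#' drift); on-time receipts land in the day bins (-14,0], (0,7], (7,28] with
#' the configured masses, and not-on-time occasions either have a late
#' receipt beyond day 28 (probability `late_receipt_prob`) or no record at
#' all (`NA`).
#'
#' @param occasions Occasion data frame (as in [generate_population()]) with
#'   an `arm` column, or with arms supplied via `arm`.
#' @param config The scenario.
#' @param arm Optional vector of arm labels (recycled) overriding
#'   `occasions$arm`.
#' @param clinic_effects,parent_effects Named lookup vectors of random
#'   effects by `clinic_id` / `parent_id`; defaults are zero. Pass the
#'   population's values for the full hierarchical structure.
#' @return Integer vector of receipt day offsets (`NA` = no record), aligned
#'   with `occasions`.
#' @export
simulate_receipt <- function(occasions, config, arm = occasions$arm,
                             clinic_effects = NULL, parent_effects = NULL) {
  n <- nrow(occasions)
  if (n == 0L) return(integer(0))
  if (is.null(arm)) stop("occasions must have an assigned arm", call. = FALSE)
  arm <- rep_len(as.character(arm), n)
  if (anyNA(match(arm, arm_table()$arm)))
    stop("unknown arm label", call. = FALSE)
  pt <- as.character(occasions$schedule_point)
  if (anyNA(match(pt, names(config$baseline_ontime))))
    stop("unknown schedule point", call. = FALSE)

  u <- if (is.null(clinic_effects)) 0 else
    unname(clinic_effects[occasions$clinic_id])
  v <- if (is.null(parent_effects)) 0 else
    unname(parent_effects[occasions$parent_id])

  early <- if ("early_vax" %in% names(occasions)) occasions$early_vax else
    stats::runif(n) < config$early_vax_prob[pt]

  eta <- stats::qlogis(config$baseline_ontime[pt]) + config$arm_log_or[arm] +
    u + v + config$epoch_drift * occasions$epoch
  ontime <- stats::runif(n) < stats::plogis(eta)

  receipt <- rep(NA_integer_, n)
  # on-time: pick a bin then a day uniformly within it
  bin <- sample.int(3L, n, replace = TRUE, prob = config$ontime_bin_probs)
  lo <- c(-14L, 1L, 8L)[bin]
  hi <- c(0L, 7L, 28L)[bin]
  day_ontime <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  # late receipts: geometric tail beyond day 28
  late <- stats::runif(n) < config$late_receipt_prob
  day_late <- 29L + stats::rgeom(n, 1 / config$late_mean_extra_days)
  # early: uniform 15-45 days before due
  day_early <- -15L - as.integer(floor(stats::runif(n) * 31))

  idx <- !early & ontime
  receipt[idx] <- day_ontime[idx]
  idx <- !early & !ontime & late
  receipt[idx] <- day_late[idx]
  receipt[early] <- day_early[early]
  receipt
}
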