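#' Decision thresholds for interim analyses
#'
#' A single posterior-probability threshold governs the superiority
#' declaration: control is discontinued when either the pooled reminder
#' effect or any individual reminder arm has `Pr(OR > 1)` at or above it.
#' The trial protocol's numeric value is not public; the default 0.99 is a
#' package choice, and [calibrate_threshold()] tunes it so the type I
#' assertion probability under the global null stays below 5%.
#'
#' @param superiority_prob Probability in (0.5, 1).
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(superiority_prob = 0.99) {
  if (!is.numeric(superiority_prob) || superiority_prob <= 0.5 ||
      superiority_prob >= 1)
    stop("superiority_prob must lie in (0.5, 1)", call. = FALSE)
  structure(list(superiority_prob = superiority_prob),
            class = "decision_thresholds")
}

#' Interim analysis trigger
#'
#' The first interim analysis fires once 1500 index occasions have
#' completed their 28 days of follow-up (about 100 parents per arm under
#' the initial 1/5 + 12 x 1/15 allocation); each subsequent analysis fires
#' after every additional 500 completed index occasions. There is no upper
#' cap in the trigger itself.
#'
#' @param n_index_complete Number of index occasions with complete
#'   follow-up.
#' @param analyses_done Number of interim analyses already performed.
#' @param first,step Trigger schedule (defaults 1500 and 500).
#' @return Logical: is an interim analysis due?
#' @export
check_interim_trigger <- function(n_index_complete, analyses_done,
                                  first = 1500L, step = 500L) {
  stopifnot(n_index_complete >= 0, analyses_done >= 0)
  n_index_complete >= first + step * analyses_done
}

#' Response-adaptive allocation targets
#'
#' Computes new target allocation probabilities for the reminder arms from
#' the current posterior summary. Each active arm gets raw weight
#' `sqrt(pr_best * var_logodds / n)` — the square root of the product of
#' its probability of being the best reminder arm, the posterior variance
#' of its conditional log-odds, and the inverse of its current sample size
#' — so allocation favours arms that look good, are imprecisely estimated,
#' or are under-sampled. Weights are normalised to total 4/5 while control
#' remains active (control is pinned at exactly 1/5) and to 1 after
#' control is dropped. Arms with `pr_best = 0` get target 0 before any
#' floor is applied.
#'
#' @param summary An [summarise_arms()] data frame (active arms only, or
#'   pass `active` to subset).
#' @param control_active Logical; is the no-SMS arm still allocated?
#' @param weight_form `"sqrt_product"` (default: the square root covers
#'   the whole product) or `"sqrt_prob_only"` (square root of `Pr(best)`
#'   only, times `var/n`).
#' @param floor Optional minimum per-arm target (applied after
#'   normalisation among positive-weight arms, then renormalised); 0 by
#'   default.
#' @return Named target vector over `c("control", reminder arms)` summing
#'   to 1; the control entry is 1/5 while active and 0 once dropped.
#' @export
compute_rar_targets <- function(summary, control_active = TRUE,
                                weight_form = c("sqrt_product",
                                                "sqrt_prob_only"),
                                floor = 0) {
  weight_form <- match.arg(weight_form)
  if (any(summary$n < 1))
    stop("every active arm must have data before RAR applies",
         call. = FALSE)
  w <- switch(weight_form,
              sqrt_product = sqrt(summary$pr_best * summary$var_logodds /
                                    summary$n),
              sqrt_prob_only = sqrt(summary$pr_best) *
                summary$var_logodds / summary$n)
  if (all(w == 0)) w <- rep(1, length(w))  # fully degenerate posterior
  sms_mass <- if (control_active) 4 / 5 else 1
  tgt <- w / sum(w) * sms_mass
  if (floor > 0) {
    pos <- w > 0
    tgt[pos] <- pmax(tgt[pos], floor * sms_mass)
    tgt[pos] <- tgt[pos] / sum(tgt[pos]) * sms_mass
  }
  stats::setNames(c(if (control_active) 1 / 5 else 0, tgt),
                  c("control", summary$arm))
}

#' Apply the stopping / discontinuation rules
#'
#' Effectiveness is declared when the pooled (shared-model) reminder
#' effect, or any single reminder arm under the primary (full) model, has
#' posterior probability of superiority over no SMS at or above the
#' threshold. Declaring effectiveness discontinues the control arm:
#' control's target goes to 0 and all subsequently randomised parents go
#' to the 12 reminder arms. The drop is absorbing — once declared it is
#' never reversed, and already-assigned parents keep their arm.
#'
#' @param arm_summary [summarise_arms()] output from the full (primary)
#'   model, active arms only.
#' @param pooled_pr_gt_1 `Pr(OR > 1)` of the pooled effect from the shared
#'   model.
#' @param thresholds A [decision_thresholds()].
#' @param analysis_index Sequence number of this interim analysis.
#' @param n_index_complete Completed index occasions at the trigger.
#' @param control_active Is control still being allocated coming in?
#' @param already_declared Has effectiveness been declared previously?
#' @param rar Recompute reminder-arm targets via [compute_rar_targets()]
#'   (default TRUE); if FALSE targets are left `NULL`.
#' @param ... Passed to [compute_rar_targets()].
#' @return A list of class `interim_decision`: `analysis_index`,
#'   `n_index_complete`, `effectiveness_declared`, `control_dropped`,
#'   `trigger` (`"pooled"`, `"arm:<label>"` or `NA`), `new_targets`,
#'   `pooled_pr_gt_1`, `max_arm_pr_gt_1`.
#' @export
apply_stopping_rules <- function(arm_summary, pooled_pr_gt_1, thresholds,
                                 analysis_index, n_index_complete,
                                 control_active = TRUE,
                                 already_declared = FALSE, rar = TRUE, ...) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  th <- thresholds$superiority_prob
  max_arm <- max(arm_summary$pr_gt_1)
  hit_pooled <- pooled_pr_gt_1 >= th
  hit_arm <- max_arm >= th
  declared <- already_declared || hit_pooled || hit_arm
  trigger <- if (already_declared) "previous" else if (hit_pooled) "pooled"
  else if (hit_arm)
    paste0("arm:", arm_summary$arm[which.max(arm_summary$pr_gt_1)])
  else NA_character_
  control_now <- control_active && !declared

  new_targets <- if (rar)
    compute_rar_targets(arm_summary, control_active = control_now, ...)
  else NULL

  structure(list(analysis_index = analysis_index,
                 n_index_complete = n_index_complete,
                 effectiveness_declared = declared,
                 control_dropped = !control_now,
                 trigger = trigger,
                 new_targets = new_targets,
                 pooled_pr_gt_1 = pooled_pr_gt_1,
                 max_arm_pr_gt_1 = max_arm),
            class = "interim_decision")
}
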