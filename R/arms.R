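#' The 13 trial arms
#'
#' The factorial layout crosses four SMS content framings (neutral, positive
#' personal-benefit, risk-based, and social-benefit) with three send timings
#' relative to the vaccine due date (14 days before, the due date itself, and
#' 7 days after), plus a no-SMS control. Control is the only arm with
#' `timing = "none"`.
#'
#' @return A data frame with 13 rows and columns `arm` (label, `"control"`
#'   first), `framing` and `timing` (factors), and `timing_offset` (integer
#'   day offset of the SMS from the due date; `NA` for control).
#' @export
#' @examples
#' arm_table()
arm_table <- function() {
  framings <- c("neutral", "positive", "risk", "social")
  timings <- c("day-14", "day0", "day+7")
  offsets <- c("day-14" = -14L, "day0" = 0L, "day+7" = 7L)
  grid <- expand.grid(framing = framings, timing = timings,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    arm = c("control", paste(grid$framing, grid$timing, sep = ":")),
    framing = factor(c("control", grid$framing),
                     levels = c("control", framings)),
    timing = factor(c("none", grid$timing), levels = c("none", timings)),
    timing_offset = c(NA_integer_, offsets[grid$timing]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @return Character vector of the 12 SMS arm labels (control excluded).
#' @rdname arm_table
#' @export
sms_arms <- function() arm_table()$arm[-1L]

#' Initial allocation targets
#'
#' The trial starts with probability 1/5 on the no-SMS control and 1/15 on
#' each of the 12 reminder arms, which induces marginal allocation 1/5 to
#' each framing and 4/15 to each timing.
#'
#' @return Named numeric vector of length 13 summing to 1.
#' @export
initial_targets <- function() {
  at <- arm_table()
  stats::setNames(c(1 / 5, rep(1 / 15, 12L)), at$arm)
}

#' Per-arm log odds ratios for a scenario
#'
#' Convenience constructor for the `arm_log_or` field of a scenario: a named
#' vector over the 13 arms with control fixed at 0.
#'
#' @param or Odds ratio(s) versus control for the 12 SMS arms; length 1
#'   (shared) or 12 (named or in `sms_arms()` order).
#' @return Named numeric vector of log odds ratios, control first and 0.
#' @export
#' @examples
#' arm_effects(1.5)   # every reminder arm at OR 1.5
arm_effects <- function(or = 1) {
  arms <- sms_arms()
  if (length(or) == 1L) or <- rep(or, 12L)
  if (length(or) != 12L)
    stop("`or` must have length 1 or 12", call. = FALSE)
  if (!is.null(names(or))) {
    if (!setequal(names(or), arms))
      stop("names of `or` must be the 12 SMS arm labels", call. = FALSE)
    or <- or[arms]
  }
  if (any(or <= 0)) stop("odds ratios must be positive", call. = FALSE)
  stats::setNames(c(0, log(or)), c("control", arms))
}
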