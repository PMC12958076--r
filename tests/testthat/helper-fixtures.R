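# Occasion-level fixture without the population machinery: one clinic,
# one schedule point, one epoch, arms drawn at the initial targets, on-time
# status Bernoulli at baseline odds times the arm's odds ratio.
make_flat_occasions <- function(n, or = 1, p0 = 0.45, seed = 1,
                                targets = initial_targets(),
                                schedule_point = 4L, epoch = 0L) {
  set.seed(seed)
  arms <- names(targets)
  arm <- sample(arms, n, replace = TRUE, prob = targets)
  lor <- arm_effects(or)[arm]
  p <- plogis(qlogis(p0) + lor)
  data.frame(
    occasion_id = sprintf("O%06d", seq_len(n)),
    parent_id = sprintf("P%06d", seq_len(n)),
    child_id = sprintf("K%06d", seq_len(n)),
    clinic_id = "C01",
    schedule_point = schedule_point,
    epoch = epoch,
    due_date = 100L,
    arm = arm,
    status = ifelse(runif(n) < p, "ontime", "not_ontime"),
    is_index = TRUE,
    stringsAsFactors = FALSE
  )
}

# Full-structure fixture through the generator: population, arms at fixed
# targets, receipts, endpoints, index flags.
make_trial_occasions <- function(n_parents = 1500, or = 1.5, seed = 1,
                                 ...) {
  cfg <- scenario_config(arm_log_or = arm_effects(or),
                         n_parents_max = n_parents, seed = seed, ...)
  pop <- generate_population(cfg)
  occ <- pop$occasions
  set.seed(seed + 1L)
  occ$arm <- sample(arm_table()$arm, nrow(occ), TRUE,
                    prob = initial_targets())
  occ$receipt_day <- simulate_receipt(
    occ, cfg,
    clinic_effects = setNames(pop$clinics$random_effect,
                              pop$clinics$clinic_id),
    parent_effects = setNames(pop$parents$random_effect,
                              pop$parents$parent_id))
  ep <- ascertain_endpoint(occ)
  occ$status <- ep$status
  occ$receipt_offset <- ep$receipt_offset
  occ <- mark_index_occasions(occ, eligible = !occ$early_vax)
  list(occasions = occ, population = pop, config = cfg)
}

table1_counts <- function() {
  utils::read.csv(system.file("extdata", "table1_index_vaccinations.csv",
                              package = "adaptsms"),
                  stringsAsFactors = FALSE)
}

# deterministic fit object with draws replaced by given constant rows,
# for closed-form checks of downstream summaries
constant_draw_fit <- function(fit, values) {
  d <- fit$draws
  d[] <- 0
  for (nm in names(values)) d[, nm] <- values[[nm]]
  fit$draws <- d
  fit
}
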