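#!/usr/bin/env Rscript
# Simulate one synthetic trial population under the default scenario,
# attach fixed-allocation arms and receipts, and write the occasion-level
# CSV that all later steps (and any external tool) can consume.

suppressMessages(library(adaptsms))
dir.create("results", showWarnings = FALSE)

cfg <- scenario_config(arm_log_or = arm_effects(1.5),
                       n_parents_max = 5000, seed = 2001)
pop <- generate_population(cfg)
print(pop)

occ <- pop$occasions
set.seed(2002)
st <- init_allocation()
occ$arm <- assign_arms(st, occ$parent_id)   # sibling-consistent by parent
occ$receipt_day <- simulate_receipt(
  occ, cfg,
  clinic_effects = setNames(pop$clinics$random_effect, pop$clinics$clinic_id),
  parent_effects = setNames(pop$parents$random_effect, pop$parents$parent_id))
ep <- ascertain_endpoint(occ)
occ$status <- ep$status
occ$receipt_offset <- ep$receipt_offset
occ <- mark_index_occasions(occ, eligible = !occ$early_vax)

excl <- exclusion_summary(occ)
cat(sprintf("\n%d scheduled occasions; %d (%d%%) excluded for early vaccination\n",
            excl$n_total, excl$n_excluded, excl$pct_excluded))
print(excl$by_schedule_point)
cat(sprintf("%d index occasions across %d parents\n",
            sum(occ$is_index), nrow(pop$parents)))

write_occasions_csv(occ, "results/occasions.csv")
write_scenario(cfg, "results/scenario.json")
cat("wrote results/occasions.csv and results/scenario.json\n")
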