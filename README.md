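# adaptsms

Simulation and analysis of a **Bayesian adaptive factorial trial of SMS
vaccination reminders**.

Routine childhood vaccines are due at fixed ages (2, 4, 6, 12, 18 and 48
months), and a substantial share of doses are given late or not at all. A
pragmatic way to nudge parents is an SMS reminder from their own clinic —
but reminders can be *framed* differently (a neutral notice, a positive
personal-benefit message, a risk-based warning, a social-benefit appeal)
and *timed* differently (14 days before the due date, on the due date, 7
days after). `adaptsms` implements the full machinery of a 13-arm
response-adaptive factorial design that compares the 4 × 3 framing-timing
combinations against a no-SMS control on **on-time vaccination**: receipt
of a scheduled dose within the window from 14 days before its due date to
28 days after. It is intended for trial statisticians and methodologists
who want to study, stress-test or adapt this class of design.

## What is in the package

* **Synthetic population generator** — clinics with random effects,
  families of 1–4 children, scheduled vaccine occasions, early-vaccination
  exclusions, calendar drift, and outcome simulation from the logistic
  model the analysis assumes (`scenario_config()`,
  `generate_population()`, `simulate_receipt()`).
* **Mass-weighted urn randomisation** — initial allocation 1/5 control +
  1/15 per reminder arm, bounded imbalance, sibling-consistent
  assignments, retargeting and permanent arm discontinuation
  (`init_allocation()`, `assign_arm()`, `retarget()`).
* **Screening, SMS and endpoint logic** — eligibility reasons, reminder
  scheduling/withholding rules, index-occasion marking and on-time
  ascertainment (`screen_eligibility()`, `schedule_sms()`,
  `ascertain_endpoint()`, `mark_index_occasions()`).
* **Five Bayesian logistic models** — full interaction, no-interaction,
  framing-only, timing-only, and a shared pooled-reminder effect, each
  adjusting for child age, calendar epoch and clinic; fast Laplace engine
  and a JAGS MCMC engine; per-arm posterior summaries including
  `Pr(best)`, and marginal standardised differences
  (`model_spec()`, `fit_posterior()`, `summarise_arms()`,
  `marginal_difference()`).

  For arm $a$ the conditional model is
  $\mathrm{logit}\,\Pr(Y=1) = \beta_0 + \lambda_a + \alpha_s + \tau_e +
  u_c$, with $\lambda_a = \beta_{f(a)} + \gamma_{t(a)} + \delta_{f(a)t(a)}$
  in the full model.
* **Adaptation** — interim triggers at 1,500 then every 500 completed
  index occasions, response-adaptive targets
  $\rho_a \propto \sqrt{\pi_a v_a / n_a}$, and the control-discontinuation
  superiority rule (`check_interim_trigger()`, `compute_rar_targets()`,
  `apply_stopping_rules()`).
* **Trial engine and operating characteristics** — whole virtual trials,
  replicate-trial power and type I assertion probability, and
  null-calibration of the superiority threshold (`run_virtual_trial()`,
  `estimate_oc()`, `calibrate_threshold()`).
* **Reporting** — arm-by-arm index-vaccination tables, exclusion
  summaries, the five-model odds-ratio grid, occasion-level CSV dialect
  (`table_one()`, `table_two()`, `exclusion_summary()`,
  `write_occasions_csv()`).

The `analysis/` directory holds numbered drivers that run the workflow
end to end (simulate → single trial → operating characteristics → report
tables), writing outputs under `results/`. The methods vignette
(`vignettes/adaptive-design-methods.Rmd`) documents the model, priors,
adaptation rules, generator assumptions and numerical choices.

## A worked example

```r
library(adaptsms)
cfg <- scenario_config(arm_log_or = arm_effects(1.5), n_parents_max = 4000)
trial <- run_virtual_trial(cfg, decision_thresholds(0.9995), seed = 11)
trial
```

```
Virtual adaptive trial: 3219 parents randomised, 4 interim analyses
  effectiveness declared: TRUE (first at interim 1)
  final pooled OR 1.67 (1.37, 2.03), Pr(>1) = 1.000
```

With every reminder arm at a true odds ratio of 1.5 versus control, the
first interim analysis (1,516 completed index occasions, simulated day
135) already finds the pooled reminder effect superior with posterior
probability 0.9998, above the 0.9995 threshold: effectiveness is declared
and the no-SMS control is discontinued, after which the urn allocates
only across the 12 reminder arms. The final pooled odds ratio of 1.67
(95% CrI 1.37–2.03) is this replicate's estimate of the common 1.5
effect conditional on clinic, age and epoch. `trial$interims` holds the
full interim trajectory and `trial$arm_counts` the per-arm allocation
and on-time counts.

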