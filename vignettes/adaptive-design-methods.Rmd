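---
title: "Methods: simulating a Bayesian adaptive factorial SMS-reminder trial"
author: "adaptsms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a Bayesian adaptive factorial SMS-reminder trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsms)
```

## The design being simulated

`adaptsms` simulates and analyses a Bayesian response-adaptive factorial
randomised trial of SMS vaccination reminders. Thirteen arms are compared:
a no-SMS control and the 4 x 3 factorial crossing of message *framing*
(neutral, positive personal-benefit, risk-based, social-benefit) with
message *timing* (14 days before the vaccine due date, on the due date, 7
days after). The unit of randomisation is the parent; the primary analysis
unit is the parent's *index vaccine occasion* — their first SMS-eligible
scheduled occasion after randomisation — and the primary endpoint is
*on-time vaccination*: receipt of the scheduled dose within the closed
window from 14 days before the due date to 28 days after. An occasion
vaccinated more than 14 days early predates any possible reminder and is
excluded; an occasion with no receipt record at the end of its 28-day
follow-up counts as not on time, so the endpoint has no missingness.

Allocation starts at 1/5 to control and 1/15 to each reminder arm (hence
1/5 per framing and 4/15 per timing) under a mass-weighted urn, and is
re-targeted at interim analyses by response-adaptive randomisation (RAR).
Control stays pinned at 1/5 until a superiority rule fires, after which it
is discontinued permanently. Interim analyses trigger at 1,500 completed
index occasions (about 100 parents per reminder arm at the initial
allocation) and every further 500.

## The outcome model and its five structures

All analyses are Bayesian logistic regressions for on-time vaccination.
For occasion $i$ with arm $a(i)$, schedule point $s(i)$ (child age 2, 4,
6, 12, 18 or 48 months), 4-week calendar epoch $e(i)$ of the due date and
clinic $c(i)$:

$$\mathrm{logit}\,\Pr(Y_i = 1) = \beta_0 + \lambda_{a(i)} + \alpha_{s(i)}
  + \tau_{e(i)} + u_{c(i)} \;[+\, v_{p(i)}]$$

with parent effects $v_p$ added for all-occasion (secondary) analyses.
The arm term $\lambda_a$ takes one of five pre-specified structures, all
fitted side by side rather than selected among:

* **full** — framing main effects, timing main effects, and
  framing-by-timing interactions (12 arm degrees of freedom; the primary
  model, and the one feeding RAR);
* **no interaction** — framing plus timing main effects only;
* **framing only**; **timing only**;
* **shared** — a single pooled any-reminder-versus-control effect, which
  supplies the "average reminder effect" used in the stopping rule.

Identifiability uses reference levels: control arm, day-14 timing and
neutral framing for the interaction block, first observed schedule point,
first observed epoch. Clinic (and parent) indicators enter without a
reference level and are shrunk by their prior instead.

**Priors.** The protocol's exact priors are not public, so defaults here
are the package's own weakly-informative choices: Normal(0, 1) on
framing/timing/interaction and pooled log-OR effects, Normal(0, 2.5) on
the intercept and the age and epoch adjustments, and scale 1 on clinic
and parent effects. All are configurable via `prior_spec()`. These keep
every posterior proper under complete separation (a warning is still
emitted when a treatment cell is all-success or all-failure).

**Engines.** `engine = "mcmc"` samples the joint posterior via JAGS and is
meant for one-shot analyses at the protocol's 10,000 draws.
`engine = "laplace"` finds the posterior mode of the penalised model by
iteratively reweighted least squares on a sparse indicator design and uses
the multivariate-normal approximation at the mode; it is two to three
orders of magnitude faster and is the default inside replicate
simulations. Both engines target the same posterior when the clinic-effect
prior scale is fixed (the default); the MCMC engine can optionally sample
that scale under a half-Normal hyperprior. A cross-engine test keeps
per-arm median odds ratios within 3% on a common fixture. Because the
Laplace posterior is exactly normal, interim stopping statistics
(`pr_positive()`) are computed from closed-form normal tails rather than
from draws — at thresholds like 0.9995 the granularity of a few thousand
Monte Carlo draws would otherwise dominate the decision.

**Marginal standardisation.** To express effects on the probability
scale, `marginal_difference()` predicts the on-time probability per draw
at the most recent calendar epoch with random effects set to zero (a
"typical" clinic and parent), averages equally over schedule points, and
differences each arm against control.

## Adaptation rules

At each interim, the reminder-arm targets become proportional to
$\sqrt{\pi_a \, v_a / n_a}$ — the square root of the product of the arm's
posterior probability of being best among active reminder arms, the
posterior variance of its conditional log-odds, and the inverse of its
sample size. The sentence defining this rule is grammatically ambiguous
about whether the square root covers the whole product or only the
probability; the package takes the whole product (the
variance-stabilised, conventional reading) and exposes the alternative as
`weight_form = "sqrt_prob_only"`. `Pr(best)` excludes control, matching
the rule's use; draws tied for best share their draw equally, so a
degenerate shared-effect posterior still yields the symmetric 1/15
targets.

Effectiveness is declared — and control discontinued — when the pooled
effect or any single reminder arm has posterior probability of
superiority at or above the threshold. The declaration is absorbing, and
control outcomes remain in all subsequent analysis datasets; only future
allocation stops.

**Threshold calibration.** The protocol's numeric threshold is not
public. `calibrate_threshold()` simulates null-scenario replicates with
the drop rule disabled, records each replicate's largest superiority
statistic across all analyses, and evaluates the whole threshold grid
against that one replicate set. This is exact, not an approximation:
under the null, a declaration affects only future allocation and the
declared flag is absorbing, so a trial declares at threshold $t$
precisely when its no-drop statistic trajectory ever reaches $t$. With
up to ~15 analyses and 13 statistics per analysis, familywise crossing
is substantial and calibration typically selects a threshold around
0.9995–0.9999 — the reason the analytic normal tails above matter.

## The synthetic population

The generator's defaults are the package's fixed study conditions:

| quantity | default | basis |
|---|---|---|
| parent cap | 10,000 | design target |
| clinics | 20 | trial's clinic count |
| family sizes 1/2/3/4 children | 0.86 / 0.13 / 0.01 / 0 | reported cohort |
| baseline on-time probability | 0.45 at every schedule point | control-arm on-time proportion; the design-evaluation scenario |
| early vaccination (> 14 d before due) | 0.32 at 2 months, 0.003 elsewhere | reproduces ~6% exclusions, ~96% of them at 2 months |
| clinic / parent effect SD (log-odds) | 0.15 / 0.25 | plausible modest heterogeneity |
| calendar drift | −0.01 per 4-week epoch | timeliness declining over the trial |
| on-time receipt-day bins (−14,0], (0,7], (7,28] | 31/118/137 of 286 | the only published timing breakdown |
| never-vaccinated share of failures | 0.5 | absence of a record is representable |
| enrolment | 40 parents/day, 420-day horizon | desk scale (below) |

Choices the design leaves open, decided once here: children's age at
enrolment is a mixture of 50% newborns and 50% uniform on 2–46 months
(families surface when a dose approaches); siblings are 1–3 years apart;
enrolment is a homogeneous Poisson process (the real trial's
clinic-onboarding waves are out of scope); late receipts beyond day 28
follow a geometric tail; early receipts fall uniformly 15–45 days before
the due date; drift is linear in epoch on the log-odds scale, the
simplest structure consistent with declining timeliness. Because a family
whose next due date falls beyond the horizon contributes no occasions,
the number of *randomised* parents in a capped run is somewhat below the
cap, as in any real enrolment window.

What the generator does **not** emulate: seasonality or weekday effects,
clinic switching, twins, vaccine-brand detail, SMS delivery failure, or
any dependence of early vaccination on the assigned arm (early receipts
precede any reminder by construction). Passing tests therefore
demonstrate that the *machinery* — randomisation, eligibility, endpoint
logic, models, adaptation — behaves as designed under a faithful
statistical structure, not that the real trial's effect estimates are
reproduced; the individual-level trial data are not public, and the
published adjusted odds ratios enter this package only as formatting
fixtures.

## Numerical choices and problem sizes

* Interim data are frozen at the simulated trigger date: only occasions
  with `due_date + 28` at or before that date enter the fit.
* Epochs with fewer than 10 observations are pooled with a neighbour
  before encoding (`min_epoch_n`).
* Replicate simulations use the Laplace engine with 2,000 draws per fit
  (draws feed RAR summaries; stopping statistics are analytic); one-shot
  analyses default to 10,000 draws.
* IRLS runs on a sparse indicator design with warm starts carried across
  interim analyses; convergence tolerance 1e-9 on the step, with step
  halving as a safeguard.
* The operating-characteristics runs in the tests and acceptance script
  use 100 null replicates for calibration and 200 replicates per scenario
  — sizes at which the binomial Monte-Carlo standard error of a declare
  rate near 0.05 or 0.85 is about 0.015–0.025, small enough to check the
  claimed 0.85 / 0.05 bounds at two standard errors.
* The mass-weighted urn keeps total mass `alpha_urn` (default 4; the
  protocol's value is not public) and draws with probability proportional
  to the positive part of each active arm's mass, giving empirical
  imbalance bounded by about `alpha_urn + 1` in all tested runs.
* Retargeting resets urn masses to `alpha_urn * target` rather than
  carrying residuals, avoiding negative-mass pathologies when targets
  shrink sharply.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(arm_log_or = arm_effects(1.5), seed = 1)
trial <- run_virtual_trial(cfg, decision_thresholds(0.9995), seed = 1)
trial
trial$interims

# operating characteristics (small demonstration sizes)
cal <- calibrate_threshold(scenario_config(), n_replicates = 100,
                           base_seed = 2)
oc <- estimate_oc(cfg, decision_thresholds(cal$threshold),
                  n_replicates = 200, base_seed = 3)
oc
```

The `analysis/` directory of the source repository runs this workflow end
to end with numbered scripts (simulate, single trial, operating
characteristics, report tables) and writes its outputs under `results/`.

## Known limitations

* The Laplace engine conditions on fixed prior scales for the random
  effects; it does not propagate uncertainty in the clinic-effect SD.
  At 20 clinics with hundreds of observations each this has negligible
  influence on arm contrasts, and the MCMC engine offers the
  hierarchical treatment.
* `Pr(best)` and RAR weights are estimated from draws; with 2,000 draws
  their Monte-Carlo error is a few per mille, which perturbs allocation
  targets slightly but not the stopping decision (analytic).
* The all-occasion secondary models estimate one coefficient per parent;
  they are intended for datasets up to a few thousand parents, not for
  the full trial scale, where the MCMC engine or a sparse-Hessian
  extension would be needed.
* Operating characteristics depend on the documented scenario defaults;
  sensitivity to baseline rates, drift and clinic heterogeneity can be
  explored by editing `scenario_config()` but is not exhaustively mapped
  here.
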