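---
title: "A lifetime Markov cohort model of ambient PM2.5 exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cohort model of ambient PM2.5 exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pmcohort` implements a deterministic Markov cohort model of the lifetime
health and healthcare-cost consequences of ambient fine particulate matter
(PM2.5) exposure for a cohort of 10,000 women aged 40, followed for 60 annual
cycles. The cohort is exposed, for life, to one of two constant
concentrations: a *standard* 15 µg/m³ (the WHO interim target 3) or an
*increased* 25 µg/m³.

Thirteen mutually exclusive, collectively exhaustive states describe four
diseases with established PM2.5 associations — lung cancer, myocardial
infarction (MI), stroke and chronic obstructive pulmonary disease (COPD):

* `event_free`;
* first-year ("tunnel") and later-year states for lung cancer, MI and stroke
  (`lc_y1`/`lc_later`, `mi_y1`/`mi_post`, `stroke_y1`/`stroke_post`), because
  costs, utilities and case fatality differ sharply between the incident year
  and the chronic phase; COPD has a single chronic state `copd`;
* five absorbing death states: `dead_lc`, `dead_chd`, `dead_cvd`,
  `dead_copd` and `dead_other`.

Each cycle, the event-free fraction moves into each disease entry state with
the age-banded annual incidence probability times an exposure multiplier, and
into `dead_other` with the background (other-cause) probability. Disease
states exit only to their cause-specific death state (age-banded case
fatality times an exposure multiplier) or to `dead_other`; first-year states
deterministically pass their survivors to the chronic state after exactly one
cycle. There are no cross-disease transitions, recurrences or remissions —
each state's occupants are at risk only of their own disease's mortality and
of background death. Competing exits within a row are additive (no
multinomial rescaling); input validation guarantees each row's total exit
probability stays at or below 1 at every age under both scenarios.

### Exposure response

Each disease contributes two relative risks (incidence and mortality), each
expressed per a concentration increment (10 µg/m³ by default, configurable
per relative risk). The multiplier applied to an annual probability under a
scenario at concentration $C$ is the log-linear extrapolation

$$ m = \mathrm{RR}^{(C - C_0)/\Delta}, $$

with reference concentration $C_0 = 15$ µg/m³ and increment $\Delta$. The
standard scenario therefore carries multiplier 1 and uses the national
incidence and mortality schedules exactly as tabulated; the increased
scenario multiplies them by $\mathrm{RR}^{10/\Delta}$. Published evidence
synthesis reports increments of 10 µg/m³ for five of the eight source studies
and 5 µg/m³ for three, without identifying which three; since they are not
identifiable, all eight default to 10 µg/m³ (the reading that keeps every
multiplier equal to its reported RR), and `per_increment` is a per-risk
configuration field so the alternative readings can be explored.

### Input schedules

The tabulated annual rates are used directly as annual transition
probabilities (the convention of the original TreeAge implementation; all
values are far below 1 except the lung-cancer case fatality 0.2109, which is
still used as printed). The actuarial conversion $1 - e^{-r t}$ is available
behind the `convert_rates` settings flag. Age bands are closed below and open
above with the terminal band open-ended; rows tabulated at decade midpoints
(45, 55, 65, 75, 85) are interpreted as decade bands [40,50), …, [80,∞).
COPD mortality, tabulated only at 75 and 85, is zero before age 70. The
cohort ages deterministically: everyone is exactly 40 at cycle 0 and
$40 + t$ at cycle $t$.

## Calibration of the unprinted inputs

Two inputs of the original analysis are not printed: the Korean female
other-cause mortality schedule and the age-specific baseline EQ-5D utilities
of the event-free population. Both are supplied parametrically and pinned to
printed outputs, in three ordered steps (`calibrate_model()`):

1. **Gompertz–Makeham level.** Background mortality has annual hazard
   $h(x) = k\,(c + a e^{b (x - 40)})$ with defaults $c = 5\times10^{-4}$ and
   $b = 0.09$ (a slope typical of adult female mortality in a low-mortality
   population). The scale $a$ is set so the *unscaled* ($k=1$)
   background-only remaining life expectancy at 40 equals the published
   lifetable value of 47.3 years.
2. **Hazard scale $k$.** With diseases switched on, $k$ is found by bracketed
   bisection so the standard scenario's undiscounted life years equal the
   published 41.34 (achieved to $10^{-3}$ years; life years are strictly
   decreasing in $k$, so the root is unique).
3. **Utility scale $u$.** The baseline utility template is piecewise constant
   by decade — 0.96, 0.94, 0.92, 0.88, 0.82 — a fixture choice representing
   the familiar gentle age decline of population EQ-5D norms. The multiplier
   $u$ (values clipped to $[0,1]$) is found so the standard scenario's
   undiscounted QALYs equal the published 32.08. Utility never feeds back
   into survival, so step 3 cannot disturb step 2 and both anchors hold
   simultaneously.

Everything downstream — all increased-scenario outputs, all cost outputs, the
sensitivity analyses and the validation rates — is then a genuine model
prediction. An alternative `table` background mode accepts an explicit
(age, probability) schedule for users with lifetable access. Whether
background mortality should be all-cause or all-cause-net-of-modelled-causes
is not decidable from the published description; calibration absorbs the
difference, and the `includes_modelled_causes` flag records the assumption.

## Rewards and discounting

Annual state costs (2020 USD) and utilities attach to the eight alive states;
one-time death costs attach to entry into the four cause-specific death
states (other-cause death carries no cost, and deaths occurring directly from
the event-free state are other-cause by construction). Rewards for cycle
$t \in \{1,\dots,60\}$ use end-of-cycle occupancy and entries, discounted by
$(1+r)^{-t}$; cycle 0 accrues nothing and there is no half-cycle correction
(none is described for the original implementation; a flag reserves the
option). Death costs are discounted at their entry cycle's factor — whether
the original discounted them is unstated; we do, and document it here.
Disease-state utilities are absolute values capped at the scaled baseline
utility of the same age, so a disease can never be better than being well.

Costs discount at 5%/year in the base case. Base-case QALYs are undiscounted:
the published 0%-discount sensitivity row reports the same QALY pair as the
base case while costs change, which identifies the base-case QALY rate as 0%.
In the discount-rate sensitivity analysis the varied rate is applied to
*both* streams, which is what reproduces the published pattern of incremental
QALYs shrinking as the rate rises.

## Sensitivity analyses

`run_owsa()` varies one parameter at a time — discount rate (0, 3, 5, 7%),
horizon (5, 10, 20, 40 years; accrual truncation without recalibration) and
each relative risk at its 95% bounds — with the calibration frozen at base
case. Two deliberate non-assertions: the incremental *cost* direction for
mortality relative risks is not asserted (longer survival in a costly disease
state can offset death costs, an inversion the published results also show
for lung-cancer mortality), and the COPD-incidence QALY direction is not
asserted (the COPD utility sits at the baseline cap, so a lower COPD risk
leaves more of the cohort exposed to the costlier competing diseases).

`run_psa()` is a second-order Monte Carlo over the 8 relative risks
(lognormal, median at the point estimate, log-SD from the CI width), 7 state
utilities (beta) and 11 costs (gamma). The source reports the distribution
families but no spread parameters for utilities and costs; the defaults are a
coefficient of variation of 0.1 for utilities and 0.2 for costs (configurable
per run via the `psa` block), standard practice when standard errors are
unreported and of the right order to produce cost dispersion around 10–20% of
the mean. Each draw samples every parameter once and evaluates both scenarios
with the same draw; draws that break exit-probability feasibility are
rejected and counted, and more than 1% rejections abort. Year-1 and later
utilities of the same disease are sampled independently, as they are listed
as separate variables. The analysis runs on a private RNG stream and is
bit-reproducible given its seed.

## Validation projections

`cause_mortality_rate()` divides cumulative entries into a death state by
person-years alive; `disease_incidence_rate()` divides entries into a disease
state by event-free person-years (the population actually at risk of a first
event — whether the published figure used that denominator or all alive
person-years is unstated; both conventions are one argument away).
Person-years use the alive-at-cycle-start convention, consistent with the
no-half-cycle engine; `midcycle = TRUE` switches to the averaged convention.

## Synthetic data and the microsimulation oracle

`random_param_set()` generates structurally faithful random inputs:
age-increasing incidence schedules, relative risks drawn in [1, 2] with
log-symmetric CIs, nonnegative costs, utilities in [0, 1], and a random
Gompertz–Makeham background. Severity `mild` keeps all probabilities small,
`paper_like` matches the order of magnitude of the packaged tables, and
`extreme` pushes rates against the feasibility boundary, then rescales so the
worst-case total exit probability is at most 0.99. The generator does *not*
emulate survey microdata, correlated parameter uncertainty, or secular trends
in mortality — so passing tests demonstrate engine correctness on valid
inputs, not epidemiological realism of arbitrary draws.

`microsim_oracle()` is an independent check on the cohort engine: it
simulates individuals by categorical draws from the transition-matrix rows
(propagating per-state counts multinomially, which is an exact simulation of
exchangeable individuals) and agrees with the deterministic trace within
binomial Monte Carlo error — at $10^6$ individuals over 10 cycles, within a
few standard errors per occupancy cell.

## Numerical choices

* Root finding uses `stats::uniroot` on monotone objectives with brackets
  grown by doubling; calibration tolerances are $10^{-3}$ years (life years)
  and $10^{-3}$ QALYs or better.
* Feasibility uses a $10^{-12}$ slack on row sums to absorb floating-point
  accumulation; occupancy conservation holds to $10^{-10}$ over 60 cycles.
* Degenerate inputs are handled explicitly: zero-width CIs give point-mass
  distributions, zero CVs bypass the beta/gamma constructors, a zero hazard
  scale gives an immortal background, and a target equal to the horizon
  calibrates to $k = 0$.
* Problem sizes in the test-suite: cohort runs use the full 60 cycles
  (milliseconds each); the microsimulation check uses $10^6$ individuals over
  10 cycles; distribution-recovery checks use $10^6$ draws; the PSA is
  exercised at a few thousand draws in tests and 10,000 in the reproduction
  script.

## Known limitations

* Exposure is constant for life; no time-varying trajectories and no
  cumulative-exposure escalation of relative risks.
* No cross-disease comorbidity: a COPD patient cannot also have a stroke.
  This understates multimorbidity at old age and is the main structural
  reason the model's absolute cost level and lung-cancer event flow sit well
  below the published base-case figures even though the calibrated survival
  and quality-of-life anchors, the short-horizon costs and the
  increased-scenario life-year/QALY predictions replicate closely. The
  published validation statistics also carry internal factor-of-ten
  inconsistencies between their per-100,000 and per-person-year forms, which
  no structural choice can reconcile; the replication tests therefore
  compare each published quantity at a documented ±10% tolerance and report
  honest failures where the gap is structural.
* Indirect and non-medical costs are out of scope, as in the source; there is
  no willingness-to-pay comparison and no acceptability-curve/EVPI machinery.
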