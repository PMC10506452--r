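---
title: "Pest kill rate demography: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pest kill rate demography: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killrate)
```

## The problem and the parameter

Predatory mites mass-reared on factitious foods (storage mites, pollen) are
only useful as biological control agents if they still kill the target pest
efficiently. The intrinsic rate of increase r_m measures how fast the
predator population grows but says nothing about prey removal. The pest
kill rate k_m transfers the same demographic logic to killing: it is the
root of the Euler–Lotka equation with age-specific predation k_x substituted
for age-specific fertility m_x,

$$\sum_x e^{-k_m x}\, l_x k_x = 1,$$

so that k_m is the per-day compounding rate of the cohort's lifetime
killing, weighting early kills more heavily than late ones exactly as the
Euler–Lotka equation weights early reproduction. The supporting quantities
are the net consumption rate $K_0 = \sum_x l_x k_x$ (prey per female per
generation, survival-corrected) and the mean predation time
$T_k = \sum_x x\, l_x k_x / \sum_x l_x k_x$.

## Schedules from daily records

The data unit is one predator-day: identity, age, alive/dead, life stage,
eggs laid, prey killed by prey stage. From a cohort of n females:

- $l_x$ = (number alive at age x) / n. With observation starting at egg
  deposition, $l_0 = 1$ and $l_x$ is non-increasing by construction.
- $m_x$, $k_x$ = means over females **alive** at age x. A dead predator
  cannot kill, so mortality enters the rates only through $l_x$; this is
  what "corrected by age-specific mortality" means operationally, and it
  keeps $l_x k_x$ equal to (total kills at age x)/n.

Conventions that were genuinely open, chosen once and switchable:

- **Age origin and pivot.** x = 0 at egg deposition; integer ages with no
  midpoint (x + ½) correction, and the exponent uses the integer age. Any
  midpoint convention shifts k_m by a factor ≈ e^(k_m/2) on K₀'s scale;
  what matters for comparisons is using one convention throughout.
- **Period partition.** Life is split at ages 9 and 29 (periods 0–9 /
  10–29 / ≥30): development plus preoviposition, a window close to the
  generation time, and residual life. The first boundary treats "day 1 to 9"
  phrasing as ages 0–9 inclusive; `period_partition()` makes the boundaries
  explicit arguments rather than constants.
- **Censoring.** A female last seen alive with no death record is treated
  as dying the next day, with a warning — in a design that follows every
  female to death, censoring is a data defect, and silently keeping such
  females would inflate late-life $l_x$.
- **Prey mortality.** No correction: natural prey survival in such arenas
  exceeds 96%, so uncorrected kill counts are attributed to predation.
- **Fecundity summaries** cover ovipositing females by default (the
  conventional reporting for period fecundity tables); `fecundity = "all"`
  includes every female alive in the period.

## Solving for the rate

For any schedule with positive net production at some positive age and
$\sum_{x=0} l_x k_x < 1$ at age 0, the residual
$f(k) = \sum_x e^{-kx} l_x k_x - 1$ is strictly decreasing, so the root is
unique. `solve_kill_rate()` brackets it with Brent's method (`uniroot`,
bracket auto-widened from [−1, 10]) and polishes with Newton steps until
$|f(k_m)| \le$ `tolerance` (default 1e−10). A schedule with $K_0 \le 1$ has
a non-positive root and is returned with a warning; $K_0 = 0$ is an error,
as is net production ≥ 1 concentrated at age 0, where no finite root exists.
The test suite checks the solver against an independent plain bisection and
against the closed form $k_m = \ln(K)/a$ for single-age schedules.

### ln(K₀)/T_k is a lower bound, not an identity

The prose identity "k_m = ln K₀ / T_k" holds only when all net predation
falls at a single age. In general, by Jensen's inequality applied to the
convex function $e^{-kx}$,

$$1 = K_0\, \mathbb{E}_w[e^{-k_m x}] \ge K_0\, e^{-k_m T_k}
\quad\Longrightarrow\quad \ln(K_0)/T_k \le k_m,$$

with a gap that grows with the spread of the net predation curve. For
realistic schedules — kills spread from the larval stage to residual life —
the gap is large: T_k ≈ 24 d against an implied single-age time
$\ln(K_0)/k_m$ ≈ 11.5 d. Published killing-parameter tables in this
literature print the implied time, which reproduces k_m through the
identity by construction. The package therefore reports three quantities
and never conflates them: `Tk` (the weighted-mean-age formula), `km_approx`
= ln(K₀)/T_k (the lower bound), and `Tk_implied` = ln(K₀)/k_m.

## Jackknife uncertainty

k_m is a nonlinear functional of the whole cohort, so its sampling error is
estimated by the leave-one-out jackknife over females: pseudovalues
$v_i = n\hat\theta - (n-1)\hat\theta_{(-i)}$, estimate = mean(v), SE =
sd(v)/√n, interval = estimate ± t(1−α/2, n−1)·SE (α default 0.05). This
interval formula reproduces, from a printed estimate ± SE with n = 15, the
corresponding printed 95% bounds exactly (0.515 ± 2.1448·0.015 →
[0.483, 0.547]). Each leave-one-out replicate re-solves the Euler–Lotka
equation on the reduced schedule; because $l_x k_x$ equals per-age summed
counts over n, the n replicates are computed from one count matrix without
re-assembling cohorts. A leave-one-out subset with zero net predation
aborts with a diagnostic naming the dropped female — silently skipping it
would bias the pseudovalue set.

## Newman–Keuls comparison

Rates from several origins are ranked and compared by the sequential
studentized-range procedure: a stretch of r adjacent ordered means is
heterogeneous when its extreme difference exceeds q(1−α; r, df); a
non-significant stretch is not subdivided, and stretches inside an accepted
homogeneous stretch are never tested. Pairs are summarised as a compact
letter display (groups sharing a letter: not separable). df pools over
groups, Σ(nᵢ−1); ties in ranked means break by label order.

The error term is the one genuinely open choice. With jackknifed nonlinear
rates the pseudovalue dispersion differs substantially between groups
(printed SEs of 0.015 vs 0.006 for equal n), so the default compares each
extreme pair on its own standard error of the difference,
$\sqrt{SE_i^2 + SE_j^2}$ (`method = "pairwise"`). A classical pooled error
term ($\sqrt{2 s^2_p / n_h}$, `method = "pooled"`) is available but, under
variance heterogeneity this strong, over-separates the low-variance groups:
on the published estimate/SE triples it cannot produce the published
letter pattern, while the pairwise term reproduces it exactly. The
procedure also inherits the dominance property that no pair is declared
different when the full-range (Tukey) test is non-significant — that is the
first test in the sequence.

## The synthetic cohort generator

`simulate_cohort()` is an individual-based emulation of the predation
life-table experiment: 15 replicate females per treatment (the default),
followed daily, preying ad libitum on a pest offered as 20 eggs + 15
immatures + 15 adults per arena-day (supply is outside the model — ad
libitum by construction).

Per female per day:

- **Survival.** Transition hazards: juveniles die with a constant daily
  hazard calibrated so egg→adult survival is `juvenile_survival`
  (default 0.9; juvenile mortality is a free parameter, not a measured
  value); adults face `adult_hazard` (default 0.005/d) until age 29, then a
  senescent hazard 1/(`residual_life_mean`+1), making the mean number of
  living days beyond age 29 equal `residual_life_mean` (13.2 / 13.5 / 11.3
  d for the Ld / Gd / Po presets).
- **Kills.** Poisson by default (`rounded_normal` with a tunable SD factor
  is available to control dispersion) with an age-specific mean: period
  means (e.g. 2.59 / 11.64 / 8.29 prey/day for Ld) are constant within
  periods 2 and 3; within period 1 a fraction `late_skew` (default 0.73) of
  the period's expected total falls on the two preoviposition days (ages
  8–9), the rest uniformly over ages 3–7. Killing starts at age 3 (larval
  emergence — this species' larvae feed); predator eggs kill nothing.
  That onset age matters: it pins the early part of the net predation
  curve, which the Euler–Lotka weighting amplifies, and with it each
  preset's large-cohort k_m lands at ≈ 0.515 / 0.52 / 0.476 per day —
  inside the published jackknife interval for the corresponding origin.
- **Stage split.** Total kills divide multinomially into prey eggs /
  immatures / adults with proportions 0.41 / 0.39 / 0.20.
- **Fecundity.** Poisson daily eggs from age 10 (first oviposition), with
  period-2 and period-3 means (2.50 / 0.71 for Ld).

Identical seed and configuration give a byte-identical cohort.

What the simulator does *not* emulate: between-female heterogeneity beyond
what the count distributions induce (real females have persistent quality
differences, making real between-female SDs larger than Poisson sampling
alone — the printed Table-style SDs are between-female SDs of means, which
a within-female Poisson model only partially reproduces), day-to-day
autocorrelation, prey-stage preference shifts with age, and any
functional-response saturation. Passing recovery tests therefore shows the
pipeline is self-consistent under the generating model, not that the model
captures every feature of laboratory data.

## Problem sizes and test design

The package's own test and reproduction runs use: 15-female cohorts for the
experiment-scale analyses (the design size), 200-female cohorts for
parameter-recovery checks (SEs small enough that a 2-SE band is a sharp
test), 50 seeded 200-female replicates for the k_m-in-interval rate, 200
seeded 15-female replicates for jackknife interval coverage against the
large-cohort (n = 3000) limiting rate, and 100 randomized schedules for
solver/oracle agreement at 1e−8. Coverage is asserted at ≥ 0.90 for a
nominal 0.95 interval — jackknife-t intervals for nonlinear rates at n = 15
are approximately, not exactly, calibrated.

## Known limitations

- k_m counts killed prey of all stages equally; it ignores energetic
  differences between killing a prey egg and a prey adult, partial
  consumption, and the contribution of predator males.
- The jackknife t-interval assumes approximately normal pseudovalues;
  for small n and strongly skewed schedules bootstrap alternatives exist
  but are out of scope.
- Newman–Keuls controls error rates stepwise and is known to be liberal
  relative to Tukey HSD for some configurations; it is provided because it
  is the field's reporting convention for these tables, not as the
  recommended general-purpose procedure.
- Period-1 daily kill means computed over living days are biased low by
  juvenile deaths when the within-period mean is age-increasing (early
  deaths sample only low-kill days); the effect vanishes under full
  juvenile survival and does not affect periods 2–3, whose means are
  constant within the period.
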