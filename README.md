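# killrate

Cohort life-table analysis of predator efficiency against a target pest.

Biological control programmes mass-rear predatory mites (Phytoseiidae) on
cheap factitious foods — storage mites or pollen — and need to know whether
predators coming off such rearings still kill the target pest (e.g. the
spider mite *Tetranychus urticae*) at full efficiency. Population growth
rate alone cannot answer that: it measures how fast the predator multiplies,
not how much prey it removes. The *pest kill rate* k_m summarises killing
capacity in a single demographic parameter, directly comparable across
rearing origins, species and conditions.

`killrate` implements the full analysis from raw observations to compared
rates: per-female daily records (survival, life stage, eggs laid, prey
killed by prey stage) → age-specific schedules → demographic rates →
jackknife uncertainty → multiple comparison. A seeded individual-based
simulator generates cohorts with the statistical structure of such an
experiment, so the whole pipeline can be exercised and tested without
access to raw laboratory data.

## The model

From a cohort of females followed daily from egg deposition (age x = 0) to
death, the package builds

- **l_x** — fraction of the cohort alive at age x,
- **m_x** — mean eggs laid per living female per day at age x,
- **k_x** — mean prey killed per living female per day at age x
  (split by prey stage: eggs / immatures / adults).

Killing is summarised by substituting predation for fertility in the
classical Euler–Lotka framework:

- net consumption rate **K₀ = Σₓ l_x k_x** — prey killed per female over a
  generation, corrected for age-specific mortality;
- mean predation time **T_k = Σₓ x·l_x·k_x / Σₓ l_x·k_x** — the mean age of
  net prey consumption;
- pest kill rate **k_m**, the unique root of **Σₓ e^(−k_m·x) l_x k_x = 1**,
  solved iteratively (Brent bracketing + Newton polish on the residual).

The same machinery applied to l_x·m_x gives R₀, the mean generation time T
and the intrinsic rate of increase r_m. `ln 2 / rate` converts either rate
into a doubling time.

Uncertainty comes from leave-one-out jackknife pseudovalues
(vᵢ = n·θ − (n−1)·θ₍₋ᵢ₎) with a t-based interval on n − 1 df; treatments are
compared with the Newman–Keuls sequential studentized-range test and
reported as a compact letter display.

## Worked example

The `analysis/` scripts run the complete study on simulated cohorts — 15
females per rearing origin (`Ld`, `Gd`, `Po` = two storage-mite rearings and
an oak-pollen rearing):

```sh
Rscript analysis/01_simulate_cohorts.R   # cohort CSVs + config YAMLs
Rscript analysis/02_life_tables.R        # lx/mx/kx tables, period summaries, figures
Rscript analysis/03_kill_rates.R         # K0, Tk, km, rm, doubling times
Rscript analysis/04_uncertainty_comparison.R  # jackknife + Newman-Keuls
```

Stage 3 prints, per treatment (seed 20230918):

```
<demographic_rates> Ld
  K0 (net consumption)        308.67 prey/female
  Tk (mean predation age)      24.02 d
  km (pest kill rate)         0.4963 /d   doubling 1.40 d
  ln(K0)/Tk                   0.2387 /d
  R0    49.93   T  22.62 d   rm  0.2278 /d   doubling 3.04 d
```

Each female removes ~309 prey over her life; the cohort's killing, weighted
as the Euler–Lotka equation weights reproduction, compounds at 0.50/day —
it would double in 1.4 days — and exceeds the predator's own growth rate
(r_m ≈ 0.23/day), the signature of an effective control agent. Stage 4
jackknifes km for each origin and compares them:

```
<jackknife_result> Ld km: 0.4967 (full 0.4963) +/- 0.0143 SE, 95% CI [0.4659, 0.5275], n = 15
<nk_comparison> Newman-Keuls sequential test, alpha = 0.05, pairwise error, df = 42
 treatment  estimate         se  n letters
        Po 0.4931502 0.02065565 15       a
        Ld 0.4967022 0.01434102 15       a
        Gd 0.5076212 0.01923121 15       a
```

All three origins share the letter `a`: at n = 15 none of the rearing diets
measurably degrades killing efficiency. The same end-to-end run is available
as a single call:

```r
library(killrate)
res <- run_pipeline(presets = c("Ld", "Gd", "Po"), outdir = "results/run", seed = 42)
```

which writes life-table CSVs, a rates report, the jackknife/comparison table
and a plain-text summary.

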