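---
title: "Modeling the population health impact of nicotine vaping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the population health impact of nicotine vaping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapersim)
```

## The model

`vapersim` is a cohort-based, discrete-time simulator of cigarette smoking
and nicotine vaping product (NVP) use. It follows a population by single age
and gender, one calendar year at a time, and compares two projections:

* a **counterfactual (No-NVP) scenario**, in which smoking prevalence
  evolves only through smoking initiation and net cessation, and
* an **NVP scenario**, in which vaping initiation, switching from smoking to
  exclusive vaping, and vaping cessation are also active.

The public health impact of vaping is the difference between the two
scenarios in smoking-(and-vaping-)attributable deaths (SADs/SVADs) and
life-years lost (LYLs).

### States and transitions

Nine mutually exclusive states cover the joint smoking/vaping history
(`use_states()`). Dual users are counted as current smokers, with smoker
mortality. The counterfactual occupies only the first four states:

| state | meaning | excess mortality |
|---|---|---|
| `never` | never established smoker or vaper | 0 |
| `current_smoker` | smokes (incl. dual use) | $\mu_c-\mu_n$ |
| `former_smoker` | quit at age 35+ | $\mu_f-\mu_n$ |
| `former_smoker_lowrisk` | quit before 35 | 0 |
| `nvp_user` | vapes, never established smoker or switched before 35 | $r(\mu_c-\mu_n)$ |
| `nvp_user_exsmoker_lowrisk` | switched before 35 | $r(\mu_c-\mu_n)$ |
| `fs_nvp_user` | quit smoking at 35+, vapes | $(\mu_f-\mu_n)+r(\mu_c-\mu_n)$ |
| `former_nvp_user` | quit vaping, no smoker-risk history | $r(\mu_f-\mu_n)$ |
| `former_nvp_user_exsmoker` | quit vaping after switching at 35+ | $(\mu_f-\mu_n)+r(\mu_f-\mu_n)$ |

Here $\mu_n,\mu_f,\mu_c$ are never/former/current-smoker death rates and
$r$ is the NVP relative-risk multiplier: NVP users' excess mortality as a
fraction of the smoking excess (default 0.05; sensitivity analyses span
0.05–0.50). The *quit-before-35 rule* gives smokers who quit or switch
before attaining age 35 never-smoker baseline mortality thereafter.

Each model year applies, in order: (1) status-specific survival
$1-\mu_s(a,g,t)$; (2) transitions among survivors (initiation, cessation,
switching, vaping cessation); (3) renormalisation of the state shares to
sum to 1. Former-smoking states are absorbing: the cessation rate is *net*
of relapse and represents permanent quitting.

### Why shares evolve and counts come from the projection

The population projection supplied by the user already embodies total
mortality. The engine therefore evolves the *composition* (state shares)
and rescales to the projected headcounts (`count_mode = "projection"`),
which avoids double-counting deaths; differential mortality still reshapes
the composition through the survival step. Whether the original spreadsheet
implementation renormalises to the projection or evolves absolute counts is
not documented; both are supported (`count_mode = "evolve"` keeps absolute
survivor counts), and the state shares are identical under either mode.

### New entrants and exits

The model window is ages 18–99. Each year a new cohort enters at the
minimum age carrying the base-year entry-age state distribution; in the NVP
scenario, from the introduction year on, its current-smoker share is scaled
by the smoking-initiation multiplier and a vaper share of
$m_{\text{nvp}} \times$ (base current share) is added, with the remainder
drawn from the never pool. This is a documented approximation — an 18+
model cannot observe initiation at younger ages directly. The oldest age
class exits after its year.

### Country adaptation

Country inputs are population projections, overall mortality, base-year
overall life expectancy and base-year smoking prevalence. Everything else
is rescaled from built-in reference (US-style) rates:

* **Age-group expansion.** Grouped mortality becomes single-age mortality
  by uniform assignment within groups (`expand_groups_uniform()`).
* **Prevalence smoothing.** Age-group prevalence is placed at group
  midpoints `floor((lo+hi)/2)`, interpolated linearly between midpoints and
  held flat outside the outer midpoints (`smooth_group_prevalence()`). For
  the German group structure this reproduces the published boundary
  behaviour (ages 18–22 take the value at 23; 83–99 the value at 82).
  Linear interpolation was chosen over splines because it is monotone
  within each segment, exact at midpoints, and trivially auditable; users
  can substitute their own single-age curve.
* **Transition scaling.** Initiation rates are multiplied by the country/
  reference ratio of current-smoking prevalence among ages 18–24, cessation
  rates by the 25–64 ratio (`scale_transition_rates()`). Band prevalences
  are population-weighted means; the country's base-year population weights
  both sides of the ratio, since reference population counts are not part
  of the input set (an unweighted mode is available). Scaled rates above 1
  are clipped with a warning rather than rejected, since ratio scaling can
  overshoot for extreme countries.
* **Mortality scaling.** Status-specific death rates are multiplied by the
  country/reference overall-mortality ratio, cell by cell — the literal
  reading of the published procedure, applied to the full rate rather than
  the excess. A common ratio preserves the ordering
  $\mu_c \ge \mu_f \ge \mu_n$.
* **Life expectancy.** Never-smoker life expectancy is the reference
  never-smoker value times the base-year country/reference overall
  life-expectancy ratio, held constant over the horizon.

### The NVP transition schedule

The five NVP-scenario flows are proportional to the counterfactual rates
(`build_schedule()`): smoking initiation at `m_smk_init` (German default
0.88), NVP initiation at `m_nvp_init` (0.25) of counterfactual smoking
initiation; smoking and NVP cessation at 1.0 of counterfactual cessation.
Switching from smoking to exclusive vaping follows an age-group/gender
schedule (`default_switch_rates()`, 0.6–4.0%/yr), scaled by
`switch_scale` (0.5) and decaying exponentially (`decay_factor` 0.9, i.e.
−10%/yr) from `decay_start_year` (2018). The published description leaves
ambiguous whether the printed schedule is pre- or post-halving; here it is
treated as the pre-loaded schedule with the halving applied on top, and
both knobs are independent so either reading is expressible. Before the
introduction year the schedule equals the counterfactual rates with all
NVP flows zero, so the NVP step reduces exactly to the counterfactual step
— a stronger and more useful reading than zeroing every flow, which would
freeze smoking dynamics before the introduction year.

Per-parameter annual change factors (`annual_change`) allow any multiplier
to drift exponentially from the introduction year; by default only
switching decays, matching the German configuration.

### Outcomes

Attributable deaths multiply each state's excess mortality by its
start-of-year headcount; LYLs weight each death by the never-smoker
remaining life expectancy at that age/gender/year. Net impact is the
counterfactual-minus-NVP difference, yearly and cumulative, with
percentages on the cumulative counterfactual totals. The excess composition
for former smokers who vape (switched at 35+) is underdetermined by the
published description; the default adds the NVP excess to the
former-smoker excess (`fsnvp_excess_mode = "additive"`), with `"nvp_only"`
as the alternative. Internal arithmetic is double precision throughout;
rounding (deaths to integers, percentages to one decimal) is applied only
at reporting.

## The synthetic-data generator

`generate_bundles()` builds a complete country + reference input pair from
parametric curves, so every operation is testable without any external
download:

* Gompertz-type never-smoker mortality ($b_0 e^{\beta a}$, doubling every
  `log(2)/0.085` ≈ 8 years), status relative risks 2.5 (current) and 1.5
  (former), and a mild secular decline (0.995/yr);
* a Gaussian-shaped initiation profile peaking at the entry age and a
  cessation rate rising linearly with age;
* base-year prevalence smoothed from age-group anchors — the published
  German group values (34.7/34.5/30.4/12.0%) split by gender, against
  US-style anchors (21.3/27.0/22.1/9.4%) for the reference population;
* a population projection evolved under the country's overall mortality;
* life expectancy computed from the mortality curves by a closed period
  life table (hazard extrapolated beyond age 99 so old-age values are not
  truncated).

The country's overall mortality is offset multiplicatively (default 1.08)
from the reference mixture, so every rescaling step has a nontrivial
effect. The generator is a deterministic function of its configuration;
the seed drives only optional jitter (off by default) and the stochastic
oracle. What the generator does **not** emulate: cohort effects in smoking
history, migration, period shocks, survey measurement error, or the
CISNET-style age-period-cohort structure of real initiation/cessation
surfaces. Tests passing on these fixtures therefore validate the model
*mechanics* — rescaling arithmetic, bookkeeping, conservation, monotone
responses — not the realism of any projection for an actual country.

The default configuration is the Germany-like preset (`germany_preset()`):
2012–2060 (48 annual steps, within the 88-year cap), ages 18–99, the
published multipliers and switching schedule. All full-scale tests and the
acceptance script run at this size; a reduced window (ages 18–50,
2012–2022) is used for unit tests where only mechanics are at stake.

## The microsimulation oracle

`microsim_oracle()` pushes up to $10^6$ individual agents through the same
annual survival-then-transition rules with pseudo-random draws and returns
state shares with binomial standard errors. It shares the *inputs* (the
per-year rate path) with the deterministic engine but none of the update
code, so agreement within Monte-Carlo error on randomized instances is a
genuine cross-check of the cohort algebra. It refuses fewer than 1,000
agents (too noisy to arbitrate) and horizons beyond 15 years (error
compounding makes the binomial standard error optimistic).

## Numerical choices and degenerate inputs

* Shares are renormalised every year; conservation is asserted at 1e-9.
* Competing flows are annual probabilities applied in a defined order, not
  competing hazards; feasibility (`smk_init + nvp_init <= 1`,
  `smk_cess + switch <= 1`) is checked and violations raise errors.
* The age-35 rule lands a transition in a low-risk substate iff the
  attained age at the end of the transition year is at most 34.
* Group expansion requires exact coverage (gaps are coverage errors,
  overlaps schema errors); smoothing with a single group degenerates to a
  constant curve.
* Scaled rates above 1 clip with a warning; zero reference denominators
  (band prevalence, overall mortality, life expectancy) are hard errors.
* Sensitivity grids never clamp negative averted values — an NVP scenario
  with halved cessation is genuinely worse than the counterfactual and is
  reported with its sign.

## Known limitations

* The counterfactual extrapolates pre-NVP initiation/cessation patterns;
  there is no mechanism for policy shocks or regulatory change.
* Dual users are not a separate state; they inherit smoker risks and
  transition behaviour entirely.
* Former-smoker risk does not decline with time since quitting beyond the
  binary quit-before-35 distinction.
* The entrant distribution at age 18 is an approximation (see above), so
  very long horizons compound an assumption about ages never modeled.
* Heated tobacco products and other novel products are out of scope.

## A worked example

```{r example, eval = FALSE}
preset <- germany_preset()
traj0 <- run_scenario(preset$bundles$country, preset$rates,
                      scenario = "no_nvp")
traj1 <- run_scenario(preset$bundles$country, preset$rates, preset$params,
                      scenario = "nvp")
out0 <- outcome_table(traj0, preset$rates, rr_nvp = 0)
out1 <- outcome_table(traj1, preset$rates)
net_impact(out0, out1)
```

See the README for the numbers this prints and the acceptance script
(`scripts/acceptance.R`) for the full set of recomputed quantities.
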