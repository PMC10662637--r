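# vapersim

Cohort simulation of the population health impact of nicotine vaping
products (NVPs).

## The problem

Policymakers weighing NVP regulation need to know whether vaping, on net,
reduces or increases population harm: exclusive vaping carries far lower
risk than smoking, but vaping also recruits people who would never have
smoked. `vapersim` answers this with a counterfactual comparison. It
projects a country's adult population (single ages, by gender, one year at
a time) under two scenarios:

* **No-NVP (counterfactual)** — smoking evolves only through initiation and
  net cessation, as if vaping never existed;
* **NVP** — vaping initiation, switching from smoking to exclusive vaping,
  and vaping cessation are also active.

The net impact is the difference in **smoking- and vaping-attributable
deaths** (SADs/SVADs) and **life-years lost** (LYLs) between the scenarios.

Attributable deaths at age $a$, gender $g$, year $t$ are

$$D(a,g,t) = \sum_s \big(\mu_s(a,g,t) - \mu_n(a,g,t)\big)\, N_s(a,g,t),$$

the per-state excess over never-smoker mortality $\mu_n$ times the state's
headcount; LYLs weight each death by a never smoker's remaining life
expectancy at that index. NVP-use states carry excess mortality equal to a
relative-risk multiplier $r$ (default 0.05) times the corresponding
smoking excess. Smokers who quit — or switch to vaping — before age 35
revert to never-smoker baseline risk ("quit-before-35 rule"); dual users
count as current smokers.

Country adaptation needs only population projections, overall mortality,
base-year life expectancy and base-year smoking prevalence; built-in
reference rates (initiation, cessation, mortality by smoking status,
switching by age group) are rescaled to the country by prevalence,
mortality and life-expectancy ratios. A synthetic-data generator produces
complete, invariant-satisfying input bundles — including a Germany-like
preset (2012–2060, ages 18–99) — so the whole pipeline runs and is tested
without any external data.

Intended users: tobacco-control researchers and modelers who want a
scriptable, testable counterpart to spreadsheet-based harm-reduction
models, and anyone needing transparent scenario/sensitivity machinery for
vaping policy questions.

## Worked example

```r
library(vapersim)

preset <- germany_preset()          # synthetic Germany-like inputs + defaults
b      <- preset$bundles$country
traj0  <- run_scenario(b, preset$rates, scenario = "no_nvp")
traj1  <- run_scenario(b, preset$rates, preset$params, scenario = "nvp")
out0   <- outcome_table(traj0, preset$rates, rr_nvp = 0)
out1   <- outcome_table(traj1, preset$rates)
net_impact(out0, out1)
```

which prints:

```
<net_impact>
  gender deaths_averted lyls_averted
1 female       44438.23      1645267
2   male       80661.74      2847963
3   both      125099.97      4493230
deaths averted: 1.7%, LYLs averted: 3.6%
```

Over 2012–2060 this synthetic population suffers 7.53 million attributable
deaths in the counterfactual (`out0$cumulative`); allowing vaping averts
about 125,100 of them (1.7%) and 4.49 million life-years (3.6%).
Population-weighted adult smoking prevalence falls from 32.8% (2012) to
12.5% (2060) for males in the NVP scenario versus 15.1% in the
counterfactual, with exclusive vaping at 3.8%:

```
> subset(traj_prevalence(traj1), year %in% c(2012, 2060))
   gender year smoking    nvp fs_nvp
1    male 2012  0.3280 0.0000  0e+00
2  female 2012  0.2377 0.0000  0e+00
97   male 2060  0.1247 0.0378  3e-04
98 female 2060  0.1052 0.0312  3e-04
```

One-at-a-time sensitivity grids (`run_sensitivity()`) rerun the NVP
scenario over relative risks and perturbed multipliers; survey validation
(`validate_against_survey()`) compares model and survey *relative* changes
in prevalence, since surveys disagree on levels.

## Command line

A thin front-end is installed under `exec/`:

```sh
vapersim run         --config config.yaml --out out/ --seed 1
vapersim sensitivity --config config.yaml --out out/
vapersim validate    --config config.yaml --out out/
vapersim synth       --config config.yaml --out bundle/
```

The YAML config selects inputs (a written bundle manifest or the synthetic
generator), scenario parameters, sensitivity and validation blocks; see
`?read_run_config`.

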