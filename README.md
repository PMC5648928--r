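# lungvct — virtual clinical trials of chemoradiation in NSCLC

`lungvct` is an in-silico trial engine for non-small cell lung cancer
(NSCLC). It simulates individual patients' tumor burdens through combined
chemoradiation and aggregates Monte Carlo cohorts into the quantity trials
actually report — Kaplan–Meier overall-survival curves — so that treatment
schedules can be compared, subgroups stratified, and population parameters
estimated before anyone runs the real trial. It is aimed at radiation
oncology and biostatistics researchers doing treatment-schedule optimization
and trial design.

## Model

Each virtual patient carries a tumor burden *N* (cell number; diameter *d*
maps to *N* via a sphere at 5.8×10⁸ cells/cm³) evolving as

```
dN/dt =  ρ N ln(K/N)          Gompertz growth toward capacity K (30 cm)
       − β_c C(t) N           log-cell-kill chemotherapy, C(t) = Cmax·2^(−t/t½)
       − (α d + β d²) N       linear-quadratic radiation per fraction, α/β = 10 Gy
```

Radiation fractions act as instantaneous survival events; drug
concentrations decay with a 24 h half-life and superpose linearly. Death
from disease occurs at a 13 cm tumor diameter; a Poisson draw
p = exp(−N_nadir) at the end of the course decides tumor control; an
independent 1.48%-per-year hazard models other-cause death; survivors are
censored at 60 months. Populations are sampled from per-stage truncated
lognormal initial volumes, a correlated (r = 0.87) positivity-truncated
bivariate normal for growth rate ρ and radiosensitivity α, and a truncated
normal for the chemotherapy effect β_c. Because Gompertz growth accelerates
as the burden shrinks, repopulation during and after therapy emerges with no
extra parameters (a kickoff-exponential variant is included for
comparison).

A three-stage fitting cascade (`fit_growth` → `fit_radiation` →
`fit_chemo`) estimates these distributions from observed monthly survival
curves under common random numbers, each stage freezing its predecessors.
See the vignette in `vignettes/virtual-trials.Rmd` for the full methods.

## Worked example

Compare concurrent against sequential chemoradiation (identical drugs,
radiotherapy from protocol day 1 vs day 50) on a simulated stage III cohort:

```r
library(lungvct)
dists <- population_distributions()

cohort <- sample_cohort(dists, c(IIIA = 0.5, IIIB = 0.5), 10000, seed = 1)
con <- simulate_cohort(cohort, build_rtog9410_concurrent(), seed = 2)
seq <- simulate_cohort(cohort, build_rtog9410_sequential(), seed = 2)

benefit <- 100 * (sf_at(km_curve(con), c(36, 60)) -
                  sf_at(km_curve(seq), c(36, 60)))
round(benefit, 1)
#> [1] 4.6 4.6

rho_stratified_benefit(cohort, con, seq, month = 36)
#>          group    n benefit
#> 1 below_median 5000  0.0076
#> 2 above_median 5000  0.0836
#> 3 top_quartile 2500  0.1204

set.seed(5)
round(median(sample_alpha_rho(1e5, dists)$alpha), 3)
#> [1] 0.161
```

Delivering the same drugs and dose concurrently instead of sequentially
gains about 4.6 percentage points of overall survival at both 3 and 5 years
in this cohort. The gain concentrates in fast-growing tumors: 8.4 points
above the growth-rate median (12.0 in the top quartile) versus 0.8 points
below it — shortening the overall treatment time matters most when the tumor
can repopulate quickly between cell kills. The sampled population's median
radiosensitivity is α ≈ 0.16 Gy⁻¹, the value the radiation-only fit
produces.

A thin command-line front end wraps the same functions
(`inst/cli/lungvct`): subcommands `simulate`, `compare-arms`, `stratify`,
`vdt-summary`, `fit`, `make-fixtures`, `make-schedule`, each taking
`--seed` and writing CSV/YAML.

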