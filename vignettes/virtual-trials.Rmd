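---
title: "Virtual clinical trials of chemoradiation in NSCLC: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual clinical trials of chemoradiation in NSCLC: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungvct)
```

`lungvct` simulates populations of non-small cell lung cancer (NSCLC)
patients through combined chemoradiation and summarizes them the way trials
are reported: as Kaplan–Meier overall-survival curves. Its purpose is
in-silico trial design — comparing schedules (sequential vs concurrent
chemoradiation), stratifying by tumor growth rate, and estimating the
population parameters that make the simulated curves match observed ones.

## The patient model

A patient's tumor is a single scalar burden: the cell number
$N = \tfrac{\pi}{6} d^3 \cdot \rho_{\mathrm{cell}}$, with diameter $d$ in cm
and density $\rho_{\mathrm{cell}} = 5.8\times10^{8}\,\mathrm{cells/cm^3}$.
The density only rescales all burdens jointly, so its exact value does not
affect fits. Three processes act on $N$:

* **Gompertz growth** toward a carrying capacity $K$ (stored as a 30 cm
  equivalent diameter):
  $\dot N = \rho\, N \ln(K_c/N)$, with $\ln$ the natural logarithm and
  $\rho$ in day$^{-1}$. The relative growth rate rises as the tumor shrinks,
  which is how accelerated repopulation during and after cytotoxic therapy
  emerges without extra parameters. An exponential variant (constant
  volume-doubling time, VDT) and a *kickoff* variant (exponential regrowth
  with a 3-day VDT from day 28 of therapy until the end of the radiation
  course) are provided for comparison.
* **Radiation**, as instantaneous linear-quadratic survival events: a
  fraction of dose $d$ multiplies $N$ by
  $\exp[-(\alpha d + \beta d^2)]$ with $\beta = \alpha/10$
  ($\alpha/\beta = 10$ Gy, the standard NSCLC assumption, fractions of at
  most 10 Gy).
* **Chemotherapy**, as log-cell kill proportional to drug concentration:
  $\dot N = -\beta_c C(t) N$, where each administration contributes an
  exponentially decaying concentration
  $C(t) = C_{\max} 2^{-t/t_{1/2}}$ ($t_{1/2} = 24$ h) and doses superpose
  linearly. Both drugs of the cisplatin/vinblastine doublet share one
  $\beta_c$, so their exposure integrals simply add.

A patient dies of disease when the burden reaches a 13 cm diameter (about 41
doublings of a just-detectable tumor). At the end of the treatment course a
single Poisson draw on the course nadir $N_{\min}$ decides tumor control
(probability $e^{-N_{\min}}$ that no clonogen survives). Other-cause death
is an independent exponential competing risk with annual hazard
$-\ln(1-0.0148)$, matching life-table survival reduction; the phrasing of a
"1.48% survival reduction" is ambiguous between one-off and annual, and the
annual reading is used because the value derives from life tables. Patients
alive at 60 months are censored. The survival clock starts at diagnosis, and
treatment begins after a uniform 14–21 day delay, because trial curves are
measured from enrollment.

## Population distributions

`population_distributions()` holds the fitted population. Initial diameters
are truncated lognormals per stage — `ln d` is normal with the tabulated
location and scale, rejected (never clipped) outside $[0.3, 13]$ cm
($[0.3, 5]$ for stage I); 0.3 cm is the detectability floor. $\rho$ and the
radiosensitivity $\alpha$ are jointly normal with correlation 0.87 on the
underlying normals (faster-growing tumors are more radiosensitive); pairs
with a non-positive component are rejected jointly, which enriches the
accepted population in fast-growing, sensitive tumors and puts the accepted
median $\alpha$ at 0.16 Gy$^{-1}$. $\beta_c$ is an independent
positive-truncated normal $(0.028, 0.0007)$ per mg/m$^3$ — essentially
deterministic across patients. Untreated cohorts (no $\alpha$ in play)
sample $\rho$ from its own positive-truncated marginal instead.

Two calibration choices deserve explanation:

* **Volume scales for stages IIIA/IIIB/IV.** The as-published scale values
  for these stages (9.40, 6.87, 8.82) are inconsistent with the fitted
  population they accompany: under the truncated-lognormal reading they
  imply ~2 cm median diameters for all three stages, whereas the fitted
  stage-wise medians are 5.06/8.74/9.68 cm. Shifting the decimal (0.940, 0.687, 0.882) reproduces
  the reported stage-wise medians *and* means to three significant figures
  (check with `truncated_lognormal_quantile()` /
  `truncated_lognormal_mean()`; the test suite pins these). The package
  defaults therefore use the corrected scales. Stage I and II scales are
  kept as printed (stage II reproduces its reported median/mean almost
  exactly; stage I sits ~6% off, a known wrinkle).
* **Natural logarithm in the growth law.** With the tabulated $\rho$
  distribution, the natural-log convention reproduces the reported
  post-induction repopulation (median 100-day VDT near 12 days) and the
  fitted $\alpha$ median of 0.16; a base-10 reading would rescale $\rho$ by
  $\ln 10$ and roughly double the post-induction VDT. Natural log is used
  throughout.

## Treatment schedules

Schedules are immutable event lists (radiation fractions, drug
administrations) with times in days from the start of therapy; protocol
"day 1" is time 0. Presets: `build_rt_only_60gy()` (60 Gy in 30 weekday
fractions — weekends off, so the course spans 40 calendar days; a
consecutive-day switch exists for sensitivity checks),
`build_rtog9410_sequential()` / `build_rtog9410_concurrent()` (cisplatin
100 mg/m$^3$ on protocol days 1 and 29, vinblastine 5 mg/m$^3$ weekly for 5
weeks, radiotherapy from day 50 or day 1), and `build_chemo_only()`
(per 28-day cycle: cisplatin on cycle day 1, vinblastine on cycle days 1 and
8 — the trial regimen is not organized in cycles, so this composition is a
documented package choice). The quoted mg/m$^3$ unit is preserved literally
and $C_{\max}$ is identified with the administered dose number, since the
fitted $\beta_c$ is only meaningful under that identification.

## Integration scheme

Outside the treatment window the model is solved in closed form: the
Gompertz trajectory, its inverse (time to reach a given burden, used for the
13 cm crossing), and the instantaneous VDT all have analytic expressions,
which the tests verify against Runge–Kutta integration and root finding.
Inside the window the integrator uses operator splitting on 0.1-day steps:
the exact Gompertz step composed with the analytic chemotherapy log-kill for
that step, with fractions applied as multiplicative events at their times.
The splitting error is second order; halving or coarsening the step between
1.0 and 0.1 days moves no survival time by more than a day (tested).
Stepping continues to seven half-lives past the last administration, after
which the analytically integrated remaining drug exposure is applied as one
terminal kill. Fractional cell numbers below one are meaningful (they feed
the Poisson control probability) and are never floored. On exact ties
between death causes, disease death takes precedence; the choice is
inconsequential for continuous times.

Two deliberate resolutions of ambiguities: the control draw happens once per
patient, on the treatment-course nadir, at the end of the course (the
conservative standard tumor-control-probability reading; the timing of
the draw has no standardized convention); and the kickoff exponential *replaces* the
Gompertz term from day 28 after therapy start until the end of the radiation
course, after which Gompertz resumes from the current burden (the
alternative — kickoff persisting indefinitely — is unstated in the
literature this mirrors).

## Monte Carlo design

One master seed derives independent sub-streams per purpose (cohort
sampling, control draws, natural deaths). Simulating two arms with the same
seed runs them on the same patients with the same uniforms — common random
numbers — so identical arms give exactly zero difference and arm contrasts
are variance-reduced. The per-patient control uniform is shared across arms
(the draws remain independent of the sampling stream); this is what makes
the zero-difference identity exact. `compare_arms()` repeats trial-size
cohorts to estimate the spread attributable to limited trial size, the way
the uncertainty of a real trial of that size would be gauged.

## The fitting cascade

Parameters are estimated in three frozen stages against observed monthly
survival curves, with the cost
$\sum_{m=1}^{60} (SF_{\mathrm{model}}(m) - SF_{\mathrm{obs}}(m))^2$:

1. **Growth** (`fit_growth`), two-stage: stage A frees
   $(K, \rho_\mu, \rho_\sigma)$ with initial volumes pinned to literature
   priors (stage I $2.5\pm2.5$, II $3.5\pm3$, III $6.6\pm3$ cm, truncated
   normal on diameter; the stage IV prior reuses the stage III values, which
   the literature does not cover); its cost sums over all supplied stage
   curves with equal weight (the pooling is a package choice). Stage B
   freezes those optima and re-fits each stage's lognormal volume
   parameters, which decouples into independent two-parameter fits.
2. **Radiation** (`fit_radiation`) frees $(\alpha_\mu, \alpha_\sigma)$
   against a radiation-only curve, correlation held fixed; fitting with the
   correlation on beats fitting with it off on curves generated with it.
3. **Chemotherapy** (`fit_chemo`) frees $(\beta_{c,\mu}, \beta_{c,\sigma})$
   against the sequential-CRT curve.

Every cost evaluation within a fit reuses the master seed, so the objective
is deterministic in the parameters and a bounded derivative-free optimizer
behaves well. The optimizer is Nelder–Mead on a logistic box transform with
best-so-far tracking; any monotone, bound-respecting derivative-free method
would do, and exceeding the budget returns the best-so-far with a flag.
`residual_surface()` exposes the objective on a grid (the $(K,
\rho_\sigma)$ valley of the growth fit is visible on synthetic targets).

## Synthetic reference curves

The clinical curves the cascade was built against live in external
publications, so `generate_reference_curves()` simulates the eight scenarios
(five untreated stages, radiation-only, sequential and concurrent CRT for
stage III) from known parameters and a fixed seed; a copy at $10^4$ patients
per curve ships under `inst/extdata/reference_curves` with a manifest, and
regeneration is byte-identical. Parameter recovery from these curves is what
the estimation tests demonstrate. The generator emulates sampling noise and
censoring structure of trial curves, but not digitization wobble,
eligibility filtering, toxicity-related dropout, or non-proportional
follow-up — passing recovery tests therefore shows the cascade is
self-consistent, not that real curves identify the parameters equally well.

## Problem sizes and test budgets

Cohorts of $10^4$ patients make survival fractions stable to about half a
percentage point and are used for the headline quantities; trial-size
repetitions use 400 patients (both arms on the same patients), matching the
scale of the reference trial's arms. Recovery tests run 2500–3000 patients
per cost evaluation with a few dozen optimizer iterations — enough for the
20–25% recovery tolerances while keeping the suite in the minutes range.

## Known limitations

* No normal-tissue toxicity: schedules that push toxicity limits will look
  better in the model than in patients.
* One scalar burden per patient; stage IV "tumor load" aggregates all
  lesions, and the carrying capacity is a shape parameter of the
  deceleration, not a physical volume.
* Cell-cycle, hypoxia/oxygen-enhancement, and fractionation-schedule effects
  beyond total dose and timing are not modeled; altered fractionation
  comparisons are out of scope.
* The chemotherapy model is log-cell kill with a shared $\beta_c$;
  regimen-specific pharmacology (e.g. Norton–Simon behavior) is not
  represented.
* Several headline predictions depend on choices that published trial
  analyses rarely document (the stage mix of "stage III" cohorts, the cycle
  composition of chemotherapy-only regimens); the package's choices are
  stated above and kept fixed rather than tuned.
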