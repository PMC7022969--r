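---
title: "Methods: trend and economic analysis of MIS adoption in dairy herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend and economic analysis of MIS adoption in dairy herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdmis)
```

## The problem

Herd management information systems (MIS) record the daily events of a
dairy operation — calvings, inseminations and confirmed conceptions, milk
weighings, clinical mastitis and lameness cases, cullings. Whether keeping
such records actually pays off is hard to quantify: there is no control
group (herds adopt voluntarily, at different times, to different depths),
and the benefit appears gradually as the farmer learns to use the
information. `herdmis` implements a complete analysis chain for this
question on longitudinal herd-event databases:

1. derive herd-year performance traits from raw event records;
2. classify each herd's depth of MIS adoption from which record
   categories it kept consistently;
3. estimate adoption-level-specific trends over the years since first
   MIS use with a mixed model that respects the repeated-measures
   structure of herd-year data;
4. convert the estimated trait trends into money with a partial budget,
   and probe its robustness with deterministic and Monte-Carlo
   sensitivity analysis.

Because the national databases this kind of analysis runs on are
proprietary, the package ships a synthetic herd-event generator with the
same statistical structure, so every stage is testable end to end.

## Herd-year traits

Six traits are computed per herd and calendar year, each as the average
over the animals, lactations or weighings observed that year:

| trait | unit | definition |
|---|---|---|
| AFC | months | birth to first calving, over first calvings that year |
| DO | days | calving to confirmed conception, over conceptions that year |
| DMY | kg | mean of all daily individual milk weighings |
| PL | years | first calving to culling, over culls that year |
| MAST | % | lactations started that year with ≥ 1 clinical mastitis event |
| LAM | % | lactations started that year with ≥ 1 lameness event |

Conventions the event data do not pin down by themselves: a month is
365.25/12 = 30.4375 days and a year 365.25 days; a lactation starts at a
CALVING event and a health event belongs to the most recent preceding
calving; DO is indexed by the conception year (not the calving year); the
herd size "in production" for a year counts distinct cows with at least
one calving, conception or weighing. Extreme herd-year values are trimmed
by per-trait min/max cut-offs before modelling. The cut-offs used by the
original national-database study are not published; the package default
is the population mean ± 4 SD, a conservative trim that removes on the
order of 10^-5 of a normal population and therefore preserves the
population moments. The limits are a plain data frame
(`default_cutoffs()`) and fully configurable; every removal is logged.

## Adoption levels

Events fall into three record categories: reproductive (BIRTH, CALVING,
CONCEPTION), productive (MILK_WEIGH, CULL — culling is scored productive
because productive life is a productive-domain trait), and health
(MASTITIS, LAMENESS). A herd is classified by which categories it kept
for at least five *consecutive* calendar years: reproductive only → LOW;
reproductive + productive → MEDIUM; all three → HIGH; anything less →
EXCLUDED. Two readings were open here and are resolved as follows:

* **Run alignment.** For MEDIUM/HIGH the qualifying runs of the different
  categories must overlap in at least five common consecutive years —
  otherwise the "same" herd would be analyzed on disjoint herd-years in
  different domains. The overlap window defines follow-up year 1.
* **Records per year.** A calendar year counts as covered when it has at
  least one record of the category (`min_records` configurable).
* **Multiple qualifying runs.** The earliest is used, since follow-up
  time is meant to start at the herd's first real use of the system.

Follow-up is capped at 10 years. Classification is monotone in record
availability: adding records can promote a herd, never demote it (a
property-based test exercises this).

## The trend model

For one trait, with `y` the herd-year value (log-transformed for MAST and
LAM), herd `h` and follow-up year `t`:

```
y_ht = x_ht' beta + b_h + e_ht
b_h  ~ N(0, sigma2_between)
Cov(e_ht, e_hs) = sigma2_within * rho^|t-s|
```

The fixed design `x` holds categorical effects for agroecological zone
(Holdridge life-zone label), predominant breed group, herd-size class
(1 = 5–19 cows, 2 = 20–39, 3 = 40–69, 4 = 70–99, 5 = ≥ 100; the 3–4
boundaries are package defaults, as only classes 1, 2 and 5 are defined
by the emulated study), five-year calendar period, adoption level,
follow-up year (categorical, 10 levels) and the adoption × follow-up
interaction. Calendar period and follow-up year are separately estimable
because herds started using the MIS in widely different calendar years.

Design decisions worth stating explicitly:

* **"Lognormal GLMM" = LMM on logs.** A lognormal response model with
  identity structure on the log scale is exactly a linear mixed model on
  the log-transformed response; no link-function machinery is involved.
  Back-transformed cell means are geometric means.
* **Zeros under the log.** Zero incidence values are possible in small
  herd-years; a configurable offset (`log_offset`, default 0.5 percentage
  points) is added to all values of the trait before the log whenever a
  zero is present, and subtracted after back-transformation.
* **Mapping of the random structure.** The package puts a random
  intercept between herds and a single AR(1) process within herds (the
  within-herd deviation and the residual are one term). A separate iid
  nugget is redundant with yearly data unless replicate measures exist
  within herd-years, which the herd-year averaging precludes.
* **Gaps in follow-up.** The AR(1) correlation is applied at power
  |Δyear|, so missing years decay the correlation correctly.
* **Estimation.** REML, with the common scale profiled out and a
  quasi-Newton (`nlminb`) search over the unconstrained transforms of
  the variance ratio and rho (log and atanh). Per-herd covariance blocks
  are grouped by follow-up-year pattern and reduced to precomputed
  cross-products, so one REML evaluation costs a few 8 × 8 solves
  regardless of herd count. A fit of 300 herds × 8 years takes well
  under a second. The fit is cross-checked in the test suite against
  `nlme::lme` with `corAR1` (same model, independent implementation) and,
  with AR(1) disabled on balanced data, against OLS on herd-demeaned
  responses.
* **Inference.** Joint Wald chi-square tests per fixed-effect term and
  Wald Z tests for the variance components (one-sided for variances,
  two-sided for rho), the latter from a central-difference Hessian of the
  unprofiled REML surface. No denominator-degrees-of-freedom correction
  is applied; with hundreds of herds the chi-square reference is
  adequate, and the parameter-recovery experiment in the test suite
  confirms ~95% coverage of the Wald intervals. This is a documented
  limitation for small populations.
* **Marginal means.** Least-squares means: the linear predictor averaged
  with equal weights over the levels of the nuisance factors for every
  adoption × follow-up cell. Equal weighting is the classical convention
  (it estimates the population-marginal mean of a balanced population);
  observed-frequency weighting would answer a different question. They
  are invariant to row order and reference-level relabelling, which is
  tested.
* **Health traits and the adoption contrast.** Under the strict
  availability pattern, MAST/LAM exist only for high-adoption herds, so
  the adoption factor is inestimable for them; `drop_single = TRUE` fits
  such traits without that factor. In real databases, lower-level herds
  typically have *some* health records (just not five consecutive
  years), which is what makes the adoption contrast estimable there.

## The synthetic generator

`sim_config()` describes the emulated population; `simulate_traits()`
draws herd-year trait values directly, and `simulate_events()` emits
animal-level event streams whose derived traits converge to the same
herd-year values as cow numbers grow.

The defaults encode the emulated study conditions: 389/343/180 herds at
low/medium/high adoption, lognormal herd sizes around 34 cows (minimum
5), trait baselines AFC 31.3 ± 4.8 months, DO 100.6 ± 16.1 days, DMY
16.7 ± 4.5 kg, PL 4.02 ± 1.45 years, MAST 10.9 ± 10.7 %, LAM
17.9 ± 17.4 %, and per-level follow-up trends matching the reported
magnitudes (for example −2 months AFC over the first four years at
medium adoption, +2 kg DMY over ten years at high adoption, declines of
5–7 days open). Where the emulated study gives no value, the defaults
are stated choices: an equal split of each trait's variance between the
between-herd and within-herd components (both matter strongly in herd
data; the exact split is unpublished), AR(1) correlation 0.6 (yearly
herd averages are strongly but not fully persistent), and first
follow-up years drawn uniformly from 1988–2008 so the calendar-period
factor is populated. Trend ramps are linear over their cited span and
*centered*, so a configured baseline is the population mean over the
whole follow-up window — which is what the emulated summary statistics
describe — rather than a year-1 anchor.

MAST and LAM are generated multiplicatively: the additive structure
(baseline + offsets + trend + herd effect + AR(1)) lives on the log
scale and the herd-year value is its exponential, guaranteeing strict
positivity; the log-scale intercept is chosen so the arithmetic mean of
the lognormal matches the configured baseline. Normal traits are
truncated at zero (the default means are 4+ SDs above zero, so the
truncation is essentially never active).

`simulate_events()` uses three animal streams per herd: a stable
production cohort (one calving per cow per year, conceptions at
calving + DO with DO drawn around the herd-year target, monthly-ish
weighings, per-lactation Bernoulli health flags at the herd-year target
incidence), a first-calver stream whose BIRTH dates are back-anchored at
calving − AFC, and a cull stream whose first calvings are back-anchored
at cull − PL. Back-anchored calvings receive health-event draws at their
calving-year incidence so the lactation denominators of MAST/LAM stay
unbiased. Only the record domains of the herd's adoption level are
emitted. Two approximations are documented rather than removed: a
conception drawn late in a year can fall into the next calendar year
while carrying the earlier year's target (bias ≪ sampling noise for
herds up to a few hundred cows), and back-dated birth/calving records
can extend a herd's apparent record history before its true first
follow-up year, exactly as historical dates do in real databases.

What passing tests on this generator do **not** show about real data:
real availability is ragged rather than deterministic by level, herds
enter and exit the database, reporting is voluntary and biased toward
reproductive events, and real trend shapes are not linear ramps. The
generator is a calibration instrument for the estimator and pipeline,
not a demographic simulation.

## Partial budget and sensitivity

The economic engine counts only what the MIS changes. Costs per year:
straight-line amortization of hardware ($700 over 5 years) and software
($700, updates every 5 years), plus additional labor — 7.6 days
(collection) and 15.2 days (entry/analysis) per year per 100 cows at a
$24.7 daily wage. Labor scales linearly and continuously with herd size;
the investments do not. Income per year: for each trait, annual change ×
economic value × cows, with the trait changes taken either from given
inputs (defaults: DO −1.02 d/yr, DMY +0.31 kg/yr — the OLS slopes of the
medium-adoption marginal means over the first five follow-up years,
which `annual_change_from_means()` recomputes from any fitted model) and
economic values from a bio-economic simulation taken as inputs
(−$2.15/d, $64.6/kg). **Accrual is non-cumulative**: each year credits
the annual gain once, giving the characteristic "$ per 5 years per 100
cows" scale (0.31 × 64.6 × 100 × 5 ≈ $10,013). A cumulative ramp would
roughly triple the figure; the non-cumulative reading is the one
consistent with the published line items, and it is the single most
consequential convention in the module. Then GM = ΔI − ΔC and
MRR = 100 × GM/ΔC. All arithmetic is kept unrounded internally; print
methods round for display. With these inputs GM ≈ $6,894 and
MRR ≈ 163.5% over five years for 100 cows, and the gross margin first
turns non-negative at 17 cows (fixed costs of $280/year against a
per-cow margin of ≈ $16.6/year).

Deterministic sensitivity re-evaluates the budget with one input moved
±10% at a time (for days open, "−10%" strengthens the improvement to
−1.12 d/yr, mirroring the convention of labelling rows by the perturbed
value). The combined hardware+software row is reported but flagged: its
published counterpart perturbs an unidentifiable $630 base. Stochastic
sensitivity draws all inputs jointly from independent uniforms spanning
±10% (the published distributions are not available), evaluates the
budget per draw, and reports Pearson correlations with GM and MRR —
interpreted by sign and ranking only, since correlation magnitudes
depend on the unpublished distributions.

## Numerical and testing notes

* Problem sizes in the test suite are chosen to exercise the estimator
  at meaningful scale while keeping the suite quick: the coverage
  experiment uses 100 replicates of 300 herds × 8 years (Wald 95%
  intervals contain each generating parameter in ≥ 90/100 replicates);
  null-calibration uses 100 replicates of 150 herds × 6 years;
  generator–deriver agreement is checked at 10/50/200 cows per herd,
  where the mean absolute deviation from truth must fall monotonically.
* Degenerate inputs: zero-variance configurations reproduce their
  expectations exactly; a REML surface that is flat at the optimum
  ("false convergence" in `nlminb`) is restarted once and then accepted;
  a variance component pinned at zero gets its Wald SE from a
  boundary-reflected Hessian and should be read qualitatively.
* `run_pipeline()` hashes every output file into its manifest; the run
  log is excluded from the hash set because it contains wall-clock
  timings. Re-running a config with the same seed reproduces identical
  hashes.

## Limitations

Beyond the generator caveats above: no Kenward–Roger/Satterthwaite
small-sample corrections; no model selection between response families
(the normal/lognormal assignment is fixed); no discounting in the
5-year budget sums; the break-even analysis varies herd size only, with
all rates held fixed; and the published correlation magnitudes of the
stochastic sensitivity are not reproducible in principle, only their
sign/rank pattern.
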