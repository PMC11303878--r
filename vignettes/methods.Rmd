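---
title: "Model structure, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the decision model: what is
computed, which conventions were genuinely open and how they were fixed,
what the synthetic machinery does and does not emulate, and what the test
suite's agreement with the published figures does and does not establish.

## The cohort model

A closed cohort of 61-year-old hypertensive adults with no cardiovascular
history is followed in annual cycles through seven states — hypertensive
(`HTN`), five chronic cardiovascular-disease states keyed by event history
(`POST_MI`, `POST_STROKE`, `POST_2MI`, `POST_2STROKE`, `POST_MI_STROKE`),
and absorbing death (`DEAD`). Cycle 0 is the intervention year: the cohort
sits in `HTN`, incurs the arm's first-year cost, and has no event risk.

**Risk annualisation.** Each arm's QRISK3 ten-year risk is the stratum
baseline plus the trial's signed score change (negative values lower risk).
The annual first-event probability assumes a constant hazard over the
decade, $p_1 = 1 - (1 - q/100)^{1/10}$, so compounding it ten times
recovers the ten-year risk exactly. The arm's score is held fixed over the
horizon: nothing in the source analysis describes effect decay, and the
constant-hazard statement implies a constant annual probability. This is an
assumption, flagged here; re-running with a decayed `qrisk_change` is a
one-line parameter edit.

**Event typing and fatality.** Events split 60/40 into strokes and heart
attacks (a proportion-of-events reading, applied on the probability scale;
at these magnitudes the rate-scale alternative differs by under $10^{-5}$),
and each type is 45% fatal. Recurrent-event risk is obtained by converting
probabilities to hazard rates, multiplying by the history-specific hazard
ratio, and converting back ($p' = 1-(1-p)^{\mathrm{HR}}$); the same
rate-scale method adjusts the case-fatality fractions, capped at 1. The
`POST_2*` and `POST_MI_STROKE` states use the matching event hazard ratios,
but any event there is fatal: the model caps non-fatal events at two. A
consequence is that the mixed-history *fatal* hazard ratios are never
needed (the two-event fatality is 1 by construction), which resolves the
absence of a published both-history fatal hazard ratio.

**Competing risks.** Within a cycle, background (non-cardiovascular)
mortality from the Kenyan life table is applied first and event
probabilities are scaled by the survival probability $1 - p_{\text{death}}$.
This guarantees each transition row sums to one without assuming a joint
rate-space model that the source does not describe. Ages advance one band
at a time (`age = start_age + cycle - 1`, band lower bounds inclusive).

**The 70–74-year mortality band.** The published life table prints 0·0 for
ages 70–74, between bands at 0.03 and 0.07 — an implausible value, most
likely a truncated entry. The package nevertheless *defaults to the value
as printed*, because the published 20-year-horizon results are consistent
with a model that used it (with the printed zero our 20-year frontier ICERs
come out at $439 and $1020 against published $372 and $1078; with a 0.05
midpoint repair they move to $522 and $1188). The loader warns at load
time, and `read_cea_parameters(fix_70_74 = TRUE)` applies the midpoint
repair for users who prefer the demographically sensible table.

## Accrual conventions

Three conventions are unstated in the source and materially affect the
small incremental quantities that ICERs are built from. Each is a settings
flag; the defaults below were chosen as the reading that reproduces the
published deterministic results, and the package reports both readings on
request.

- **Half-cycle correction** (`half_cycle_correction`, default on):
  state-occupancy accruals use the trapezoidal average of start- and
  end-of-cycle occupancy. One-off accruals (event costs, the cycle-0
  intervention cost) are never corrected — they are flows, not occupancies.
  With the flag off, accrual uses end-of-cycle occupancy, which is also the
  convention of the microsimulation oracle.
- **Cycle-0 accrual** (`cycle0_accrual`, default on): the intervention year
  is a year lived with managed hypertension — participants receive usual
  care and medication throughout — so it accrues the hypertension
  management cost and the no-CVD disability weight, undiscounted. Without
  it the usual-care ten-year total falls about 9% below the published $793;
  with it the model gives $789.8.
- **Fatal-event one-off accruals** (`fatal_event_accrual`, default off):
  only non-fatal events incur the hospitalisation cost and the acute
  28-day disability decrement. The acute weights are duration-weighted over
  a convalescence that a fatally struck person does not live through, and
  the published incremental results are consistent with this reading (the
  population frontier ICERs reproduce within 4%; attaching the one-offs to
  fatal events as well drops them 15–25% low).

Death accrues a DALY of 1 per cycle until the end of the horizon and is
discounted like every other accrual ("costs and benefits" alike). Chronic
states carry the chronic-management cost *instead of* (not on top of) the
hypertension-management cost. The acute event decrement is added on top of
the destination state's weight in the event cycle; whether the published
model netted it out of the chronic weight is unknowable from the text, and
at 0.01 DALY it is immaterial. Discounting is
$(1.03)^{-(k-1)}$ — the first model year is undiscounted ("beyond the
first year"). In the recurrent-cost scenario the subsequent-year
intervention cost is charged, discounted, in cycles 1–9, for ten delivery
years in total; it is charged per enrolled participant regardless of vital
status, matching the per-participant costing of the delivery programme.

## Ranking and dominance

Arms sort by total discounted cost. Strict (weak) dominance removes any arm
another single arm beats on both cost and DALYs (ties resolved
deterministically by name); extended dominance then iteratively removes
arms until adjacent frontier ICERs strictly increase. The implementation is
checked against a brute-force geometric oracle — an arm is off the frontier
exactly when some convex combination of two other arms attains its DALYs at
lower cost — on randomized instances. Net monetary benefit uses
$\mathrm{INMB} = \lambda \cdot \Delta\mathrm{DALYs} - \Delta\mathrm{cost}$
and is zero exactly at the pairwise ICER.

The willingness-to-pay default is $3360 per DALY averted. The source
describes its threshold as twice GDP per capita but prints $1040 as one
times and $3360 as two times GDP — mutually inconsistent; $3360 is adopted
as the stated two-times figure and `settings$wtp` makes it explicit
input rather than a buried constant.

## Sensitivity analysis

**One-way DSA.** Every parameter with a published range (34 in the default
registry) is set to its low and high bound in turn, the four-arm model is
re-run, and the INMB of the comparison arm versus usual care is recorded;
bars sort by width. Parameters published without ranges (baseline QRISK3,
mortality, sex-stratified effects) are excluded, mirroring the source's
whole-cohort-only sensitivity scope. Cost ranges are varied one at a time
(standard one-way practice); the published fatal-MI-after-stroke range
(1.03–1.43) excludes its base value 1.00 and is loaded as printed with a
warning. Threshold analysis bisects the arm's QRISK3 change until the INMB
against its frontier comparator is within $0.01 of zero; an independent
root-finder agrees to $10^{-4}$ in the tests.

**PSA.** Families follow the source: normal for QRISK3 score changes,
gamma for costs, beta for disability weights, log-normal for hazard ratios
and the event/fatality proportions — all moment-matched on the natural
scale with mean equal to the base value. SDs come from published 95% CIs
where they exist (range width / 3.92, treating the published range as the
CI) and 10% of the base value otherwise. Log-normally sampled proportions
are truncated at 1 with a warning (their support is unbounded; the source
is silent). Draws are independent across parameters — only marginal
families are described — and a master seed spawns per-draw substream seeds,
so any subset of draws reproduces independently of execution order. The
discount rate and baseline risks are not sampled (no family is given for
them; they remain DSA-only). At 10 000 iterations the PSA takes on the
order of a minute on one CPU; the acceptability curves report, per
willingness-to-pay value, each arm's probability of attaining the maximal
net monetary benefit, ties split equally.

## Synthetic cohort and the microsimulation oracle

`generate_cohort()` emulates the trial's composition: sex
Bernoulli(0.699 female), and per-sex QRISK3 scores from a gamma
distribution (positive support, right skew — typical of risk scores)
moment-matched to the published means with the individual-level SD backed
out of the CI of the mean at the per-sex trial size
($\mathrm{SD} = \sqrt{n} \cdot \text{half-width} / 1.96$). It does **not**
emulate cluster randomization, recruitment pathways, loss to follow-up, or
covariate structure — it exists so sex-stratified and validation runs need
no external data, not as a re-creation of the trial.

`microsim_oracle()` is the repository's central correctness check: it
pushes individuals through the same transition probabilities and accrual
rules by per-individual random draws, sharing no code with the trace
algebra (no occupancy vectors, no matrix products). With half-cycle
correction off the cohort totals must match the microsimulation means
within Monte Carlo error; the tests assert agreement within 3 standard
errors for every arm and stratum at n = 30 000–40 000. With the correction
on, the two legitimately differ by a bounded timing adjustment — the
correction is an accrual convention, not a change of probabilities.

Because the generator draws from idealized distributions matched to
printed summary statistics, passing tests demonstrate internal consistency
and faithful implementation of the published inputs — not that the model
would reproduce results computed from the raw trial records.

## Numerical choices and problem sizes

Transition rows are validated to sum to 1 within $10^{-12}$ and occupancy
rows within $10^{-10}$. Beta moment-matching infeasibility (SD too large
for the mean) is clamped with a warning; it cannot occur at the default
10% SDs. Equal-cost ties in the frontier sort break by DALYs then name, so
output is deterministic. Bisection stops at $|\mathrm{INMB}| < \$0.01$ or
an interval of $10^{-10}$.

Default test-suite sizes — 30 000–40 000 microsimulated individuals for
oracle checks, a few hundred PSA draws for distributional checks, 100–200
randomized frontier instances — were chosen so the full suite completes in
well under a minute while keeping Monte Carlo bounds meaningful; the
published-scale 10 000-draw PSA remains a one-line call.

## Known limitations

- The three accrual conventions above are inferences; the published model
  is not available to confirm them. Two published quantities resist
  reproduction under any convention setting: the $7 incremental cost of
  group medical visits (we obtain $9.05 — a $2 gap on ~$790 totals, i.e.
  under 0.3% of either total) and the women's $311 group-medical-visits
  ICER (we obtain $608; its published incremental cost is $3, so sub-0.5%
  perturbations of either total move this ratio severalfold). The 20-year
  group-medical-visits ICER lands at $439 versus $372 published (+18%).
  These are reported as computed.
- Constant hazard over 10 (and, in the scenario, 20) years understates
  late-life cardiovascular risk; the source makes the same assumption and
  argues incremental results are insensitive to it.
- No correlation between sampled PSA parameters; no time-varying
  intervention effects; no equity weighting or cross-programme league
  tables.
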