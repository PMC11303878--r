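# htncea

Markov cohort cost-effectiveness analysis of community-based hypertension
care strategies in rural Kenya.

## The problem

Hypertension is the leading modifiable driver of cardiovascular disease in
low- and middle-income countries, yet blood-pressure control in rural Kenya
remains poor. A cluster-randomised trial in western Kenya compared usual
chronic-disease care against three community-integrated delivery strategies —
group medical visits, microfinance savings groups, and their combination
(GMV–MF) — and measured their effect on ten-year cardiovascular risk
(QRISK3 scores). This package implements the decision model that turns those
effect estimates, activity-based intervention costs, and local
epidemiological inputs into incremental cost-effectiveness ratios (ICERs),
so the analysis can be reproduced, stress-tested, and re-run under new
assumptions.

It is written for health economists and epidemiologists who want a
transparent, scriptable alternative to a closed spreadsheet/TreeAge model:
every input is a field of a validated parameter object, every convention is
a documented switch, and an independent microsimulation oracle checks the
cohort algebra.

## The model

A cohort of hypertensive 61-year-olds (no cardiovascular history) moves
annually through seven states: hypertensive (HTN), five chronic
cardiovascular-disease states keyed by event history (one MI, one stroke,
two MIs, two strokes, one of each), and death. Per cycle:

- The arm-specific QRISK3 ten-year risk *q* (baseline plus the trial's
  signed score change) is annualised under a constant hazard,
  *p*₁ = 1 − (1 − q/100)^(1/10); 60% of events are strokes, 40% heart
  attacks, each 45% fatal.
- Recurrent-event risk is scaled on the hazard scale,
  *p'* = 1 − (1 − p)^HR, with history-specific hazard ratios; a third
  event is always fatal.
- Background non-cardiovascular mortality comes from Kenyan life-table age
  bands and competes with event risk (events scaled by survival of
  background death).
- Costs (hypertension management $68/yr, chronic CVD management $125/yr,
  hospitalisation $1996 per MI / $1874 per stroke, intervention costs
  $87–139 in year 1) and DALYs (state disability weights 0.06–0.49, death
  weight 1, acute event decrement 0.01) accrue per cycle with trapezoidal
  half-cycle correction and 3% annual discounting beyond the first year.

Arms are ranked by total discounted cost; strictly and extended-dominated
arms are removed and adjacent frontier ICERs (US$ per DALY averted)
reported. Uncertainty is handled by one-way deterministic sensitivity
analysis (tornado of incremental net monetary benefit), threshold analysis
on the QRISK3 effect, and a 10 000-iteration probabilistic sensitivity
analysis with cost-effectiveness acceptability curves.

## Worked example

```r
library(htncea)

params <- read_cea_parameters()   # packaged base-case inputs
res <- run_cea(params)            # population stratum, 10-year horizon
summary(res)
```

```
Stratum: population | horizon 10 cycles | discount 3% | config 124b4700

                  arm total_cost incr_cost total_DALYs DALYs_averted               ICER
           usual_care       $790        ..       1.637            ..                 ..
 group_medical_visits       $799        $9       1.631         0.006              $1498
         microfinance       $819       $20       1.630         0.001 extended_dominated
               gmv_mf       $833       $14       1.620         0.009              $3170

Pairwise ICER vs usual care: group_medical_visits $1498, microfinance $3909, gmv_mf $2575
```

Reading this: group medical visits cost $9 more per person than usual care
over ten years and avert 0.006 DALYs, an ICER of about $1500 per DALY
averted. Microfinance is extended dominated (a mix of group medical visits
and GMV–MF achieves more health at equal or lower cost). The combined
GMV–MF arm buys further DALYs at roughly $3200 each relative to group
medical visits, and about $2600 each relative to usual care.

Sensitivity machinery:

```r
tor <- tornado_analysis(params, arm = "gmv_mf")      # one-way DSA
plot(tor)
threshold_effect("group_medical_visits", params)      # effect size where INMB = 0
psa <- run_psa(params, n = 10000, seed = 1)           # ~1-2 min on one CPU
plot(ceac(psa, unlist(params$settings$wtp_grid)))     # acceptability curves
oracle_check(params, n = 50000)                       # cohort vs microsimulation
```

Scenario switches live in `params$settings`: `horizon` (10 or 20 cycles),
`stratum` (`population`, `men`, `women`), `recurrent_intervention_costs`
(ten delivery years instead of one), `half_cycle_correction`,
`cycle0_accrual`, and `fatal_event_accrual` (accrual conventions, see the
methods vignette). A command-line front end with `base-case`, `dsa`, `psa`,
`oracle-check`, and `make-cohort` subcommands is installed at
`inst/cli/htncea.R`.

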