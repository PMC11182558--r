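# gpsim

Stock-and-flow simulation of online group polarization (GP) in
public-health emergencies.

When an emergency breaks, users pour into the online public opinion
field, split into positive and negative camps by social comparison,
interact, and — under information uncertainty and the pressure of
concurrent events — some radicalise into negative extreme opinions.
`gpsim` is for researchers and analysts in infodemiology, risk
communication and emergency management who want to explore how
intervention levers (government response, emotional guidance,
heat/traffic reduction) shape that process, without access to
experiments on real crowds.

## The model

A system-dynamics compartment model in continuous time (units:
persons, days). Seven opinion stocks — `P`, `PI`, `PIP` (positive:
silent, interacting, retained-and-retired), `N`, `NI` (negative:
silent, interacting), `NIN` (negative non-extreme), `NE` (negative
extreme) — plus an undecided pool, coupled by eleven flows such as

```
v4  = NI / T_e                                  (radicalisation)
v5  = NI * lambda2 / T_c                        (emotional guidance)
v7  = PI * lambda4 * min(1, NIN/NE) / (T_c T_e) (event coupling)
v10 = NIN * lambda4 / T_e * min(NIN/NE, cap)    (escalation)
v11 = NE * lambda3 / T_ef                       (heat reduction)
```

with six intervention/context fractions `lambda1..lambda6`, five time
constants, a delayed entry schedule, a lifecycle exit hazard
`h(t) = t / exit_scale_days` and threshold-latched intervention
timing (heat reduction only acts once extreme opinions exist). The GP
risk of a scenario is the peak of `NE(t)`. Persons are conserved
exactly; integration is explicit Euler with per-stock clamping; a
stochastic mode draws the opinion-allocation and escalation gates
from a seeded RNG. See the vignette
(`vignettes/polarization-dynamics.Rmd`) for the full model account.

## Worked example

```r
library(gpsim)
library(dplyr)

traj <- run_gp(baseline_scenario())
glance(traj)
#> # A tibble: 1 × 7
#>   gp_risk ne_peak_day ne_half_decay_day entered_total exited_total horizon mode
#>     <dbl>       <dbl>             <dbl>         <dbl>        <dbl>   <int> <chr>
#> 1    31.6        20.0              43.9          80.0         76.6     100 mean…
```

Of the 80 users who enter the field (100 minus the 20% kept away by
the government response), extreme opinions peak at 31.6 persons on
day 20 and have halved by day 44. Per-compartment summaries show the
"silent spiral": the positive stocks peak early (day 3.8) and collapse
while the negative-extreme stock is still growing.

```r
tidy(traj) |> filter(compartment %in% c("P", "PI", "NE", "NIN"))
#> # A tibble: 4 × 5
#>   compartment  peak t_peak decay_t    final
#>   <chr>       <dbl>  <dbl>   <dbl>    <dbl>
#> 1 P           38.7    3.75    10.3 1.11e-11
#> 2 PI           9.99   5.83    12.7 5.19e-12
#> 3 NE          31.6   20.0     43.9 3.57e- 1
#> 4 NIN         22.6   14.1     34.4 9.34e- 2
```

One-at-a-time sensitivity of the risk indicator to heat reduction:

```r
sw <- oat_sweep(baseline_scenario(), "lambda3", value_range(0.1, 0.9, 0.2))
sw |> select(value, NE_peak, NE_peak_day, NE_half_decay_day)
#> # A tibble: 5 × 4
#>   value NE_peak NE_peak_day NE_half_decay_day
#>   <dbl>   <dbl>       <dbl>             <dbl>
#> 1   0.1    36.9        22.8              54.5
#> 2   0.3    33.0        20.7              45.9
#> 3   0.5    30.4        19.6              42.5
#> 4   0.7    28.4        18.9              40.6
#> 5   0.9    26.8        18.5              39.3

percent_reduction(sw$NE_peak[1], sw$NE_peak[5])
#> [1] 27.3...
```

Strong traffic limiting cuts the extreme-opinion peak by 27% and
brings both the peak and its half-decay forward — it shortens the
life of the polarization episode. `autoplot(traj)` and `autoplot(sw)`
draw the evolution curves and the sweep.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/gpsim.R baseline --out scenario.yaml
Rscript inst/cli/gpsim.R run --config scenario.yaml --out traj.csv
Rscript inst/cli/gpsim.R sweep --config scenario.yaml --param lambda3 \
        --min 0.1 --max 0.9 --step 0.1 --out sweep.csv
Rscript inst/cli/gpsim.R summarize --traj traj.csv --out summary.tsv
```

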