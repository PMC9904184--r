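# fermkin

Quantifying forage carbohydrate digestion in horses from two complementary
assays: the **in vitro gas production technique** (IVGPT) and the **mobile
nylon-bag technique** (MBT). The package turns raw instrument output —
vented headspace pressure traces and bag recovery records — into the
kinetic and digestibility summaries nutritionists actually compare:
asymptotic gas production, half-time, time of maximum digestion rate, dry
matter and per-nutrient disappearance, transit time, recovery rates,
washing loss, and the common-slope regression of disappearance on
residence time. Seeded synthetic-data generators emulate both experiments,
so the entire pipeline runs and is tested without any animal data.

## The models

**Gas kinetics.** An automated system records gauge pressure every 10
minutes for 48 h and vents the bottle whenever pressure exceeds 0.75 psi.
Cumulative gas is reconstructed as current gauge pressure plus all vented
pressure, converted by the ideal gas law n = pV/RT and the molar volume
(22,400 mL/mol), and normalised per gram of substrate dry matter. The
curve is fitted with the monophasic sigmoidal model

    G(t) = A / (1 + (B/t)^C)

where A is the asymptotic (maximum) gas production in mL/g DM, B the time
(h) at which half of A is reached, and C a dimensionless shape constant.
The time of maximum rate of digestion is t_RM = B (C − 1)^(1/C), defined
for C > 1.

**Mobile bags.** Feed-filled porous bags (15 or 36 µm pore) transit the
stomach and small intestine and are recovered hourly from the caecum for
10 h, later ones from faeces. Transit time is the recovery-fraction
weighted mean of check midpoints, Σ tᵢMᵢ. Residues are pooled by
grass × harvest × pore × recovery interval (1–3, 4–6, 7–10 h); nutrient
disappearance is 100·(in − out)/in on a DM basis. Per-bag dry matter
disappearance over residence time is summarised by an ANCOVA with one
shared slope and per-group intercepts:

    dDM = b·t + a_(grass × harvest)

## Worked example

```r
library(fermkin)

## simulate an incubation of early vs late perennial ryegrass, fit every bottle
sc  <- gas_scenario(truth = default_gas_truth()[c(4, 10), ], n_replicates = 3, seed = 42)
sim <- simulate_incubation(sc)
fit_gas_study(sim$traces, sc$constants,
              substrate = setNames(sim$bottles$substrate, sim$bottles$bottle_id))
#>     bottle_id   A    B    C t_rm converged
#> 1 PR_early_r1 195 8.06 1.65 6.21      TRUE
#> 2 PR_early_r2 186 7.96 1.81 7.09      TRUE
#> 3 PR_early_r3 167 7.79 1.65 6.02      TRUE
#> 4  PR_late_r1 132 7.63 1.38 3.79      TRUE
#> 5  PR_late_r2 136 7.48 1.32 3.14      TRUE
#> 6  PR_late_r3 129 7.20 1.41 3.81      TRUE

## simulate and analyse a full mobile-bag study (352 bags)
bs  <- simulate_bag_study(bag_scenario(seed = 42))
res <- analyze_bag_study(bs$bags, bs$residues, bs$feeds)
res$summary
#>   transit_time_h caecal_recovery_pct total_recovery_pct
#> 1           4.63                78.8               97.2
res$regression
#> Common-slope regression of ddm on midpoint_h (252 points, 4 groups)
#>   CF.early     ddm = 0.4415 midpoint_h + 35.66
#>   CF.late      ddm = 0.4415 midpoint_h + 22.11
#>   PR.early     ddm = 0.4415 midpoint_h + 38.57
#>   PR.late      ddm = 0.4415 midpoint_h + 33.25
#>   R-squared 0.9094, residual sd 1.992
```

Early-harvest bottles produce more gas (higher A) and digest later in the
incubation (higher t_RM) than late-harvest bottles; in the bag study, bags
stay precaecal for ~4.7 h on average, ~78% are recovered through the
cannula, and dry matter disappearance rises with residence time at a
shared rate while the intercept — the instantly soluble fraction — differs
by feed.

A thin command-line driver over the same functions lives in
`inst/cli/fermkin.R` (subcommands `simulate-gas`, `simulate-bags`,
`simulate-feeds`, `fit-gas`, `analyze-bags`, `select-feeds`, `report`).

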