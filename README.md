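# subsidysim

Bioeconomic simulation of fisheries subsidy reform.

Governments pay the fishing sector roughly $35 billion a year, and most of
those payments lower fishing costs or raise revenues — capacity-enhancing
subsidies that push fleets toward overcapacity and overfishing. WTO
negotiators weighing reform packages ("disciplines" prohibiting classes of
subsidies to particular vessels or countries) need a transparent way to
compare packages by their likely effect on fish stocks, catches, revenue and
fishing pressure. `subsidysim` is for analysts doing that comparison: it
turns a vessel database, a country subsidy table and a reform proposal into
projected percent changes versus a business-as-usual (BAU) world where
subsidy provisioning never changes.

## The model

The global fishery is one aggregate Pella–Tomlinson stock harvested by four
fleets — managed/open-access crossed with reform-affected/unaffected (M-A,
M-U, OA-A, OA-U):

- biomass: `b[t+1] = b[t] + ((φ+1)/φ) g b[t] (1 − (b[t]/K)^φ) − h[t]`, with
  `g = (MSY/K)(φ+1)^(1/φ)`
- harvest: `h[j,t] = q[j] b[t] e[j,t]`, catchability calibrated as
  `q[j] = h[j,0] / (b0 e[j,0])`
- price: constant-elasticity inverse demand, `p[t] = p0 (h[t]/h0)^(1/ε)`
  with `ε < 0`
- profit: `π[j,t] = p[t] h[j,t] − α[j] e[j,t]^β + s[j,t] e[j,t]`, with
  `α[j]` set so base-year profit is exactly zero (subsidies lower costs)
- effort: `e[j,t+1] = max(0, λ[j] π[j,t] + e[j,t])`, `λ = η` for open-access
  fleets, `λ = ω ≪ η` for managed fleets

Reform removes (effective, type-weighted) subsidies from the vessels a
proposal's disciplines select; affected fleets start the projection with
negative profits and shed effort, the stock recovers, and unaffected fleets
may expand into the recovery — the rebound effect the four-fleet structure
exists to capture. Everything upstream of the model (effort-weighted
allocation of catch/revenue/subsidies to vessels in kWh terms, management
tiers, discipline predicates, cap-and-tier rules) is implemented and
documented in the methods vignette (`vignettes/subsidy-reform-model.Rmd`).

## Worked example

The allocation arithmetic on the textbook example — a flag state providing
$2M of subsidies over 15M kWh of fleet effort:

```r
library(subsidysim)
compute_flag_subsidy_rate(2e6, 15e6)
#> [1] 0.1333333        # USD/kWh, i.e. $0.133
```

A full scenario on the shipped synthetic world (400 vessels, 12 flag
states) under the default reform — prohibiting subsidies to fishing on
overfished stocks (stock status below 1), removing all capacity-enhancing
types:

```r
ds  <- default_scenario()
run <- run_scenario(ds$inputs$vessels, ds$inputs$subsidies,
                    ds$inputs$production, ds$params, ds$proposal)
run
#> <scenario_run 'Overfished stocks (B/B_MSY < 1)'>
#> Fleet sizes: M-U=99 M-A=101 OA-U=104 OA-A=96
#> Change at horizon vs BAU (%):
#>   biomass              +1.392
#>   catch                -0.619
#>   revenue              -0.103
#>   fishing_mortality    -1.983
```

Read: about half the synthetic fleet fishes overfished areas and loses its
capacity-enhancing subsidies; by 2050 the stock is 1.4% larger than under
BAU, fishing pressure is 2% lower, and aggregate catch and revenue are
slightly down because the affected fleets' exit outweighs the unaffected
fleets' rebound over this horizon. `run$bau` and `run$reform` hold the full
annual trajectories; `run$fleets` the calibrated fleet table.

There is also a command-line interface (`inst/cli/subsidysim`) with
`generate`, `run` and `compare` subcommands over CSV/JSON files, and a
library of example proposal configurations under
`inst/extdata/proposals/` (IUU list prohibition, overfished-stock rules at
two stringency levels, a 95% high-seas threshold, a 3%/5% cap-and-tier
scheme, and the ambitious full removal of capacity-enhancing subsidies).

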