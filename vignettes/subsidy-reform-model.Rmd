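---
title: "A four-fleet bioeconomic model of fisheries subsidy reform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-fleet bioeconomic model of fisheries subsidy reform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsidysim)
```

`subsidysim` projects what happens to a globally aggregated fishery when
governments withdraw some of the roughly \$35 billion they pay the fishing
sector each year. The policy question it serves is concrete: reform packages
under negotiation at the WTO differ in *which* vessels lose *which*
subsidies, and negotiators need a transparent way to rank packages by their
likely biological and economic consequences. The package chains three
pieces: a vessel-level accounting layer that attaches catches, landed value
and subsidies to individual vessels; a policy engine that turns reform
disciplines into subsidy removals; and an annual bioeconomic simulation that
compares each reform to a business-as-usual (BAU) counterfactual in which
base-year subsidy provisioning continues unchanged.

## The model

**Biology.** The world's marine fisheries are treated as one aggregate stock
with asymmetric surplus production (the Pella–Tomlinson form),

$$ b_{t+1} = b_t + \tfrac{\varphi+1}{\varphi}\, g\, b_t
   \left(1-\left(\tfrac{b_t}{K}\right)^{\varphi}\right) - h_t , $$

where $b_t$ is biomass (t), $K$ the carrying capacity, $\varphi > 0$ the
production-curve asymmetry and $h_t$ the total harvest. Production peaks at
$b = K(\varphi+1)^{-1/\varphi}$, and the growth rate is tied to maximum
sustainable yield by $g = (MSY/K)(\varphi+1)^{1/\varphi}$, so the model can
be parameterized directly from an $MSY$ estimate. The biomass update is
floored at zero, and should the fleets attempt to harvest more than the
stock plus its growth in a single year, harvests are scaled down
proportionally (preserving fleet shares) before the floor applies — a purely
numerical guard that never engages near equilibrium.

**Harvest and fleets.** Four fleets harvest the common stock:
managed/open-access crossed with reform-affected/unaffected (`M-A`, `M-U`,
`OA-A`, `OA-U`). Fleet harvest is $h_{j,t} = q_j b_t e_{j,t}$ with effort
$e_{j,t}$ in kWh; catchability is calibrated from the base year,
$q_j = h_{j,0} / (b_0 e_{j,0})$, with $b_0$ the shared global base-year
biomass.

**Demand.** Price responds to total harvest through a constant-elasticity
inverse demand. We calibrate the demand constant as
$\delta = h_0 p_0^{\varepsilon}$ and evaluate the price through the
equivalent calibration identity $p_t = p_0 (h_t/h_0)^{1/\varepsilon}$, which
returns $p_0$ exactly at the base-year harvest and is decreasing in harvest
for $\varepsilon < 0$ (configuration validation rejects non-negative
elasticities). Evaluating through the ratio form rather than through
$\delta^{-1/\varepsilon} h^{1/\varepsilon}$ keeps the two printed forms of
the demand curve mutually consistent and is numerically better behaved for
extreme $\delta$. Prices are evaluated at a floor of $10^{-6} h_0$ when
harvest collapses, with a warning, to avoid the singularity at zero.

**Costs, profits and effort.** Fleet costs are
$c_{j,t} = \alpha_j e_{j,t}^{\beta}$ and profits
$\pi_{j,t} = p_t h_{j,t} - c_{j,t} + s_{j,t} e_{j,t}$, where $s_{j,t}$ is
the *effective* subsidy rate in USD/kWh. The cost coefficient is calibrated
under the assumption that base-year profits are zero:
$\alpha_j = (p_0 h_{j,0} + s_{j,0} e_{j,0}) / e_{j,0}^{\beta}$, which makes
explicit that subsidies artificially lower operating costs. Effort then
adjusts in proportion to profit,
$e_{j,t+1} = \max(0,\ \lambda_j \pi_{j,t} + e_{j,t})$, with
$\lambda_j = \eta$ for open-access fleets and $\lambda_j = \omega \ll \eta$
for managed fleets, where effort and profit are largely decoupled by
management. Because calibration zeroes base-year profits, BAU starts at
rest; removing subsidies from the affected fleets makes their base-year
profits exactly $-\Delta s_j\, e_{j,0}$ negative, effort exits, biomass
recovers, price and catchability feedbacks then raise the profits of the
*unaffected* fleets, whose effort expands — the rebound effect that limits
what a partial reform can deliver.

**Update order.** Within a year: harvest, then price, then costs/profits,
then the biomass update (using current-year harvest), then the effort update
(using current-year profit). The alternative timing (pricing at lagged
harvest) differs only at second order near equilibrium; the order above
keeps every base-year identity exact, which is what makes the BAU
counterfactual a clean fixed point.

## From vessels to fleets

The accounting layer mirrors how global effort data are married to landings
and subsidy statistics in practice. Per flag state, subsidies divided by
total fleet effort give a subsidy rate in USD/kWh (e.g. \$2M over 15M kWh is
\$0.133/kWh); per (flag state, FAO major area), catch and landed value
divided by effort give rates in t/kWh and USD/kWh (0.5M t and \$1M over 5M
kWh give 0.1 t/kWh and \$0.2/kWh). Multiplying rates back onto each vessel's
effort allocates totals proportionally, so country and regional sums are
conserved to rounding error — a property the test suite checks on databases
of up to 10,000 vessels. Monetary amounts are carried in 2018 USD throughout
and never converted.

Because a dollar of fuel subsidy does not move fishing effort as much as a
dollar of, say, a buyback programme, nominal subsidies are rescaled by
type-specific multipliers ("effective subsidies") before entering the model.
The shipped default sets every multiplier to 1 — the package deliberately
does not invent effort-effect normalizations — and a weights configuration
file accepts externally derived values (e.g. OECD-style effort-effect
estimates).

Vessels are split into managed and open-access tiers at a quantile of their
management scores (default: the 50% quantile). Two conventions needed
fixing: the empirical quantile uses the *higher* order-statistic
(`sorted[ceiling((n-1)p)+1]`), and ties at the threshold classify as
managed. Together these make the default split put exactly the top half of
an even, distinct-scored fleet into the managed tier, make "all scores
equal" degenerate to "all managed", and make an extreme threshold such as
0.99 isolate exactly the top vessel. A lower-interpolation quantile fails
the first of these, which is why the higher convention was chosen.

## The policy engine

A *discipline* is a predicate over vessel behaviour plus a removal scope; a
*proposal* is a set of disciplines with an optional country-level cap rule.
The predicate vocabulary covers the main negotiating families: IUU listing,
fishing where stocks are overfished (a B/B\_MSY-like status, strict `<` as
in "less than 1"), time-share thresholds on the high seas or in distant
waters (`>=`, as in "at least 95%"), disputed areas, development status, and
an `always` predicate for the ambitious full-removal reference scenario.
Special and differential treatment is an exemption list of development
statuses that overrides any predicate.

Removal follows two rules: IUU and overfished disciplines remove *all*
capacity-enhancing subsidy types from triggering vessels; overcapacity
disciplines remove exactly the *listed* types — regardless of their
capacity-enhancing flag, since a listed type is prohibited as such. When
several disciplines trigger on one vessel the removed type set is the union,
so no dollar is removed twice. Cap-and-tier rules act on countries instead:
each flag state is tiered by development status, its permissible
(non-green-box) subsidies are capped at a tier percentage of either current
subsidies or landed value, and the excess is removed pro rata across its
vessels' allocations. Where a discipline and a cap both touch a type, the
per-type removal fraction is the maximum of the two mechanisms, preserving
the never-remove-twice rule. An `removal_fraction` argument scales all
removals, which is how the monotonicity experiments below vary reform
intensity without changing the affected set.

Fleet subsidy rates follow directly: $s_{j,0}$ is the fleet's effective
subsidies per unit effort, and the post-reform rate subtracts the effective
dollars removed. BAU keeps $s_{j,0}$ for every fleet indefinitely; under
reform the two affected fleets carry their reduced rates (constant over the
projection) while the unaffected fleets retain all of their original
subsidies.

## The synthetic world

All inputs can be generated offline. The generator aims at *structural*
realism — the shapes the pipeline assumes — and explicitly not at matching
real-world distributions. Its defaults describe 400 vessels under 12 flag
states fishing 8 FAO areas: per-vessel annual effort is lognormal around
2.5 million kWh (heavy right tail, as vessel-level kWh data show); country
subsidy intensities are lognormal around 0.2 USD/kWh, bracketing the
0.13 USD/kWh of the worked allocation example; catch rates are lognormal
around $1.1\times10^{-3}$ t/kWh so that total harvest lands near the
sustainable yield of the default biology; management scores are Beta(2, 2);
stock status is lognormal around 1 so that roughly half the fleet fishes
overfished areas; and the high-seas time fraction is a mixture with mass at
zero (most vessels never leave EEZs), mass forced to at least 0.95
(dedicated high-seas vessels, so the 95%/5% thresholds in high-seas
disciplines are exercised), and a uniform body.

Categorical attributes — IUU listing, disputed-area flags, dedicated
high-seas status, development tiers of flag states — are assigned by
deterministic quota (shuffle, then label the first `round(n * fraction)`)
rather than independent Bernoulli draws, so fixture counts are exact and
tests can assert them without slack. Each generator call runs in its own
seeded RNG stream (offsets of the configuration seed per generator) and
leaves the global RNG state untouched; identical configurations produce
byte-identical CSV output.

What passing tests on this world do *not* show: that the magnitudes of
projected reform effects transfer to the real fishery. Real vessel
databases have strong flag-state concentration, gear-specific effort
patterns, spatial price structure and reporting error, none of which the
generator attempts; the synthetic results validate the *mechanics*
(allocation conservation, calibration identities, dynamic signs and
orderings), not empirical effect sizes.

The ten-vessel worked fixture is hand-built rather than drawn: five vessels
in managed areas, five in open access, equal subsidy totals in the two
groups, with one managed and two open-access vessels IUU-listed. Under the
IUU discipline the partition is M-U = 4, M-A = 1, OA-U = 3 and OA-A = 2. A
narrated version of this example counts OA-A as one vessel even though its
own criterion flags two; the fixture follows the criterion and the package
asserts 2, documenting rather than silently resolving the discrepancy.

## Default parameters

The shipped biological and economic constants are illustrative values for
the synthetic world, chosen once for internal consistency rather than
estimated for any real fishery:

| parameter | default | units | why |
|---|---|---|---|
| $\varphi$ | 0.188 | — | puts the most productive biomass at $0.4K$, a common surplus-production asymmetry |
| $K$ | $5\times10^7$ | t | sets the scale of the synthetic stock |
| $MSY$ | $2\times10^6$ | t/yr | implies $g = 0.1$/yr; the generator's expected harvest (~1.9M t) sits just below the sustainable yield at $b_0$ |
| $b_0$ | $2.5\times10^7$ | t | $1.25\,B_{MSY}$: a moderately healthy aggregate stock, so BAU drifts only mildly |
| $\varepsilon$ | $-1.2$ | — | elastic enough that reform-induced supply drops raise price visibly, keeping the rebound channel active |
| $p_0$ | 1500 | USD/t | a round global-average ex-vessel price scale |
| $\beta$ | 1.3 | — | mildly convex costs; $\beta = 1$ would make marginal profit effort-independent and the open-access dynamics neutrally stable |
| $\eta$ | 0.2 | kWh/USD | scales first-year open-access effort exit to a few percent per year for the default removal shock; well inside the stability bound $\eta\,|\partial\pi/\partial e| < 2$ |
| $\omega$ | 0.005 | kWh/USD | 40× slower than $\eta$, implementing $\omega \ll \eta$ |
| years | 2018–2050 | — | base year and horizon of all projections |

The default reform scenario pairs this world with an overfished-stocks
discipline (status below 1, all capacity-enhancing types removed). It
populates all four fleets (roughly half the vessels trigger), which is what
the qualitative checks need: affected effort must fall, managed must fall
proportionally less than open-access, at least one unaffected fleet must
rebound past its BAU effort, and the biomass gain must be monotone over
removal fractions 0/25/50/100%.

## Numerical choices and degenerate inputs

* Empty fleets carry zero effort, $q = \alpha = 0$, and are inert: their
  profit is identically zero so they never re-enter.
* A fleet with subsidies but no effort is an error (no rate exists), as is
  any (flag, region) production cell without observed effort.
* Zero-vessel databases are valid for generation and I/O; tier assignment
  and allocation require at least one vessel.
* The projection aborts with a diagnostic state dump if any state variable
  becomes non-finite (e.g. under absurd adjustment speeds); it does not try
  to continue.
* `round(n * fraction)` quotas use R's banker's rounding; tests pin the
  resulting counts.
* Bit-for-bit BAU equivalence of a null reform holds because the reform
  branch differs only in the subsidy-rate vector, which is numerically
  identical when nothing is removed — no separate code path is taken.

## Problem sizes in the shipped checks

The test suite runs the calibration identities at 100 random draws each,
conservation on a 10,000-vessel database, the dynamics oracle on a two-fleet,
four-year toy, and the qualitative reform experiments on the 400-vessel
default world over 33 years; the whole suite completes in well under a
minute, and `scripts/acceptance.R` recomputes the headline quantities in a
few seconds.

## Known limitations

Single global stock — no regional structure, no stochastic recruitment, no
age or size structure; demand is a single constant-elasticity curve, so the
model is not a market forecast; subsidy removal is instantaneous and
permanent at the start of the projection; management scores, stock status
and IUU listing are taken as given vessel attributes (no upstream remote
sensing, gear inference or stock assessment); and effect magnitudes on
synthetic data carry no empirical weight. The design intent is strategic
comparison of reform packages under one transparent set of assumptions, not
tactical prediction for any fishery.
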