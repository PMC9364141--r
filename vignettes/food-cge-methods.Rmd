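---
title: "Methods: a desk-scale CGE model of beef replacement in the food system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale CGE model of beef replacement in the food system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodcge)
```

## Purpose and scope

`foodcge` is a stylized, fully self-contained computable general
equilibrium (CGE) model of a small open economy with a disaggregated beef
value chain, together with an environmental satellite account and a
synthetic benchmark generator. It is built to study beef-replacement
questions in general equilibrium: when households shift expenditure away
from beef — towards plant-based alternatives or towards the rest of their
food bundle — how do output, employment, trade, emissions, water and
fertiliser use, and animal numbers respond once all markets re-clear?

The package deliberately works at desk scale: a 15-sector economy that
solves in about a second, rather than a several-hundred-sector national
database that requires licensed data and a specialised solver. Detailed
national models of this class produce specific national magnitudes; this
package reproduces the *mechanisms* — demand substitution inside nested
preferences, cost pass-through along the value chain, export buffering,
factor reallocation — on a transparent, regenerable benchmark, so every
claim in the test suite can be verified from first principles.

## The benchmark data: a social accounting matrix

A social accounting matrix (SAM) records one year of monetary flows as a
square matrix over accounts. The package fixes the orientation as
**rows receive, columns pay** (conventions differ across databases, so the
choice is stated here and enforced everywhere): an activity's column pays
for its intermediate inputs and factors; its row receives the value of its
output from the paired commodity account; the household receives factor
income and pays for consumption and savings; the export/import accounts
settle against the rest of the world. An account is balanced when receipts
equal outlays; `balance_residuals()` measures this per account and the
default tolerance is *relative* — `1e-6` of the grand total — because SAM
cells span six orders of magnitude.

`ras_balance()` implements classical biproportional (RAS) fitting by
alternating row and column scaling. Scaling can never turn a zero cell
positive, so the input-output sparsity pattern — which determines which
CES nests exist — is invariant by construction. Infeasible support
patterns (a positive target on an all-zero margin) and non-convergence are
reported as errors carrying the last residual.

## Functional forms

Every aggregator in the model is a CES node in **calibrated share form**.
For children with prices $p_i$, substitution elasticity $\sigma$, share
parameters $\delta_i$ ($\sum_i \delta_i = 1$) and taste multipliers $t_i$:

$$P = \Big(\sum_i \tilde\delta_i\, p_i^{1-\sigma}\Big)^{1/(1-\sigma)},
\qquad
q_i = \tilde\delta_i \left(\frac{P}{p_i}\right)^{\sigma}\frac{E}{P},
\qquad
\tilde\delta_i = \frac{t_i \delta_i}{\sum_j t_j \delta_j},$$

with $\sigma = 1$ evaluated as the Cobb–Douglas limit and $\sigma = 0$ as
Leontief. This form has two properties the package depends on:

1. **Calibration is unique and trivial.** At unit benchmark prices the
   expenditure share of child $i$ equals $\delta_i$ for *every* $\sigma$,
   so `calibrate_ces_node()` just reads shares off the SAM and benchmark
   replication is exact, not approximate.
2. **Preference shocks are exact.** Taste multipliers re-weight the
   shares and renormalize them back onto the simplex, so a shock is a pure
   preference twist with no scale effect, and target expenditure shares
   can be hit exactly at benchmark prices by setting
   $t_i = \delta_i'/\delta_i$.

Household preferences are a nested CES utility tree rather than a linear
expenditure system. The choice is deliberate: CES keeps calibration
transparent (one elasticity and the benchmark shares per nest determine
everything) and the per-nest elasticities are fully config-driven, so
LES-like low expenditure elasticity for food can be approximated by a low
top-nest $\sigma$. No econometric estimation is attempted.

## Nesting structure

Production (per sector): a fixed-proportions top nest over the value-added
composite and one intermediate composite per input commodity, with a CES
value-added nest over labour, capital and (for farm sectors) land.
Intermediates are Leontief because year-scale input substitution between,
say, cattle and electricity inside beef processing is not an interesting
margin here; value-added substitution is.

Household utility (top to bottom):

- food vs non-food ($\sigma = 0.35$ by default — food demand is
  expenditure-inelastic);
- inside food: meat composite vs plant-based alternative vs other foods
  ($\sigma = 0.8$);
- inside meat: beef vs other animal products ($\sigma = 2.0$ — cooked-meat
  substitution is easy);
- other foods: a $\sigma = 1$ (Cobb–Douglas) sub-nest over dairy, grains,
  fruit & nut, vegetables, other crops, processed oils and sugar, and food
  services.

These defaults live in `default_config()` and are config-overridable; they
are round-number values in the range demand meta-analyses report for the
respective margins, chosen once when the package was designed. The
15-sector taxonomy carries a single combined "other animal"
farming/processing pair rather than separate poultry and pork sectors;
the meat nest is therefore {beef, other animal products}, and the chicken
and pig head-count satellites share the combined sector's output change.
Splitting the pair would refine the head-count split but change nothing
about the beef-side mechanics that the package exists to expose.

Armington trade: each commodity's domestic absorption is a CES composite
($\sigma = 2.0$ default) of the domestic variety and imports at world
prices. Export demand is constant-elasticity,
$E_i = E_i^0 (p_i/PFX)^{-\eta_i}$, with $\eta = 4$ for agriculture and
food commodities and $\eta = 2$ elsewhere by default. Because the detailed
trade assumptions behind any particular national implementation are not
reproducible here, `trade_sensitivity()` sweeps $\eta$ explicitly rather
than defending one value.

## Equilibrium, closure, numeraire

Unknowns: commodity prices, activity levels, factor prices, household
income, and an exchange-rate variable `PFX` that scales world prices.
Equations: zero profit per sector, market clearing for each domestic
commodity (domestic sales plus exports equal output), factor market
clearing, household income = factor payments, and the numeraire. The
external-balance equation is implied by the others (Walras' law); it is
dropped from the solved system and reported by `check_walras()` as a
diagnostic on every solution.

Two closures are provided rather than guessing which one a published
figure used:

- `full_employment` (default): aggregate factor supplies fixed, factors
  mobile across sectors, factor prices clear markets. Aggregate employment
  change is identically zero; labour "shifts from contracting to expanding
  sectors".
- `sticky_wage`: the real wage (in CPI units) is fixed and aggregate
  employment becomes endogenous, allowing economy-wide employment
  responses.

The numeraire is the benchmark-consumption-weighted consumer price index,
so all reported changes are real in CPI units; the equilibrium is
homogeneous of degree zero in the numeraire target, and the test suite
verifies that doubling it doubles every nominal variable and moves no
quantity. Savings are a fixed share of income read off the SAM's savings
account; investment spends them with fixed value shares. Government is
absorbed into the household — a documented simplification of the default
taxonomy, not a constraint of the code.

## Solvers and numerical choices

`solve_levels()` is a damped Newton iteration on the *logs* of all
variables (positivity for free) with a forward finite-difference Jacobian
(`h = 1e-7`), step-halving damping, convergence at max relative residual
`1e-9`, and an iteration trace attached to any failure. At 15 sectors the
system has 37 unknowns and solves in a few Newton steps; an analytic
Jacobian would be premature at this size.

`solve_johansen()` is the percent-change alternative: one step is the pure
linearized (Johansen) solution, exactly proportional to the shock;
`n_steps > 1` re-linearizes along an Euler path and converges to the
levels solution, with optional Richardson extrapolation. Its main role is
as an independent cross-check on `solve_levels()` — the two approach each
other as steps grow, which the test suite asserts at 1, 4, 8 and 16 steps.

Degenerate inputs are handled explicitly: zero-expenditure CES children
are dropped with a warning at calibration (their demand is identically
zero); commodities without imports skip the Armington node; sectors
without land payments get a two-factor value-added nest.

## Scenario construction

A replacement rate $r$ and a target (`plant_based` or `other_foods`)
define target leaf expenditures at benchmark prices: beef scaled by
$1-r$, the freed expenditure added to the plant-based leaf or spread over
the remaining food leaves proportionally to their benchmark expenditures
(the "current consumption bundle" reading — other meats included, which
is what makes the BEEF10 scenario expand poultry and pork directly).
Node-level taste multipliers that reproduce those shares exactly are then
computed bottom-up; everything above the food nest keeps multipliers of 1,
so food vs non-food expenditure is untouched — the shift is symmetric by
construction, and a property test verifies expenditure conservation to
`1e-10` across rates and targets. The shock is applied to the household
beef node only; the upstream cattle contraction emerges through the value
chain rather than being imposed.

## The environmental satellite account

The packaged baseline (`load_baseline_footprint()`) is a per-commodity
table of annual direct resource use of US agricultural production — blue
water (km³), nitrogen and phosphorus application (kt), greenhouse gases
(Mt CO₂eq). Its column totals (94, 10,067, 1,636, 347) are
regression-locked in the test suite. Two conventions matter:

- **NA is not zero.** Animal rows carry NA water/N/P because those inputs
  are accounted for under the feed crops that use them; soya-oil and sugar
  processing carry explicit zeros. Totals ignore NA; a dimension with no
  data at all (cropland ships empty) is reported "unavailable", never 0.
- **Linear linkage on gross output.** `apply_output_changes()` scales each
  row by its mapped sector's percent output change — coefficients are per
  unit of production, so footprints follow gross output, not value added.
  The mapping is explicit; a sector with a nonzero change and no mapping
  entry is an error, and discarding a sector requires mapping it to
  `"none"`.

Animal head counts scale the same way from baselines of 8.5 billion
chickens, 75 million pigs (midpoint of the reported 70–80 million range)
and 30 million cattle. The cattle figure is *derived*, not measured: it is
back-solved so simulated output contractions translate into head-count
declines of the reported order, is labelled as such, and is overridable.
No life-cycle assessment of the plant-based product itself is computed;
pesticides, pastureland and biodiversity have no packaged baseline and are
out of scope.

## The synthetic benchmark

`economy_template()` + `generate_sam()` produce the study conditions:
a balanced 15-sector SAM (cattle ranching, beef processing, other animal
farming and processing, dairy, four crop sectors, other crops, soya oil,
sugar, plant-based manufacturing, food services, rest of economy; labour,
capital, land) with a grand total of the order of 2×10⁷ million USD/yr.
Generation is a deterministic share skeleton plus seeded multiplicative
lognormal noise (sdlog 0.05 by default) on the technology and demand
coefficients, a feasibility repair that scales back over-used intermediate
deliveries, and a final RAS polish — feasibility by construction, not
rejection sampling.

What the generator pins (and noise never touches): beef exports at 12% of
beef-sector output; 1.0 million workers in cattle operations and 0.5
million in animal processing; agriculture below 2% and the food system
near 11% of employment; positive household expenditure on every utility
leaf so all nests calibrate; a small plant-based sector (about 1% of meat
expenditure) so the ALTP scenarios have a calibratable target. Worker
counts are template constants; hours are proportional to the SAM's labour
payments. A property test regenerates 20 seeds and re-measures the
structural shares; another verifies every generated benchmark calibrates
and solves back to itself with zero changes.

What the synthetic economy does **not** emulate: taxes and margins as
separate accounts (the stylized taxonomy omits them — flagged, not
guessed), a government sector, regional structure, multi-year dynamics,
and the several-hundred-sector detail of national databases. Passing tests
therefore demonstrate the mechanisms and the code's correctness on a
plausible food-system structure; they do not reproduce any specific
national point estimate, and the few externally anchored numbers the
package does reproduce (the footprint baseline totals and linkage, the
structural shares) are exactly the ones the acceptance script recomputes.

## Problem sizes and runtimes

The default model (15 sectors, 37 unknowns) solves a scenario in about a
second; the full test suite — including the 100-draw CES-vs-optimizer
property, 20-seed generator sweep, Johansen convergence at four step
counts, and all four scenarios — runs in about a minute on one CPU. These
sizes were chosen so that the package's own account of itself is cheap to
re-verify.

## Known limitations

- Comparative statics only; no adoption dynamics or price-parity paths
  for the plant-based product (treated as exogenous preference shifts).
- The combined other-animal sector cannot distinguish chicken-vs-pig
  substitution; head-count splits inherit one output change.
- CES everywhere: no inferior goods, no habit formation; cross-price
  structure is whatever the nesting implies.
- Finite-difference Jacobians limit the practical model size to a few
  dozen sectors — intentional for this package's purpose.
- The cattle head-count baseline is derived, and the footprint linkage is
  linear in output with fixed coefficients: no intensification or
  technology response.
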