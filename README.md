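# foodcge

A desk-scale computable general equilibrium (CGE) model of a food-system
economy, built to study what happens across a whole economy — not just the
beef sector — when households replace part of their beef demand with
plant-based alternatives or with other foods.

Static analyses of dietary change count the resources embodied in the
foregone beef and stop there. A general-equilibrium treatment instead lets
the rest of the economy respond: cattle and beef-processing output contract,
the land, labour and feed grain they release get re-priced and reallocated,
other animal sectors expand because their input costs fall, exports absorb
part of the demand decline, and an environmental satellite account converts
the resulting sector-output changes into changes in greenhouse gases, blue
water, fertiliser application, and animal head counts. The headline
qualitative findings — emissions fall, but less than the static accounting
suggests; water and fertiliser use can *rise*; chickens and pigs multiply
when beef is replaced by other foods rather than by plant-based products —
all come from these adjustment channels.

## What is in the package

- **SAM handling** (`sam()`, `read_sam()`, `ras_balance()`,
  `aggregate_accounts()`): square social accounting matrices (rows receive,
  columns pay), validation, biproportional (RAS) balancing that preserves
  structural zeros, and kind-safe aggregation.
- **Nested CES trees** (`ces_node()`, `calibrate_ces_node()`,
  `ces_demand()`, `ces_price_index()`, `build_default_trees()`): calibrated
  share-form CES aggregators. Production is Leontief over intermediates and
  a CES value-added nest; household utility nests food vs non-food, then
  {meat, plant-based alternative, other foods}, then beef vs other meat.
- **Equilibrium** (`build_model()`, `solve_levels()`, `solve_johansen()`,
  `check_walras()`, `gdp_and_aggregates()`): zero profit, market clearing,
  income balance, constant-elasticity export demand, Armington imports, CPI
  numeraire; a damped-Newton levels solver and a Johansen/Euler
  percent-change solver; full-employment and sticky-wage closures.
- **Scenarios** (`scenario()`, `build_beef_replacement_shock()`,
  `run_scenario()`, `trade_sensitivity()`, `compare_scenarios()`): BEEF10,
  ALTP10/30/60 — expenditure-preserving preference shifts that cut household
  beef expenditure by 10/30/60% at benchmark prices and reallocate it inside
  the food nest, leaving food vs non-food expenditure untouched.
- **Footprint satellite** (`load_baseline_footprint()`,
  `apply_output_changes()`, `animal_numbers()`, `share_report()`): a
  packaged per-commodity baseline of US agricultural resource use (94 km³
  blue water, 10,067 kt N, 1,636 kt P, 347 Mt CO₂eq per year) scaled
  linearly by simulated sector-output changes, plus animal head-count
  linkage (8.5 billion chickens, 75 million pigs, 30 million cattle
  baselines).
- **Synthetic data** (`economy_template()`, `generate_sam()`,
  `generate_employment_satellite()`, `perturb_sam()`): seeded, balanced
  15-sector benchmark SAMs that reproduce the structural facts of the US
  food system by construction — beef exports 12% of beef output, ~1 million
  workers in cattle operations and 0.5 million in animal processing,
  agriculture under 2% and the food system ~11% of employment.
- **Pipeline** (`cmd_run()`, `cmd_footprint()`,
  `write_synthetic_economy()`, plus the `inst/scripts/foodcge` wrapper):
  config-driven runs writing tidy CSV reports with config hashes and solver
  diagnostics.

## The model in brief

Every aggregator is a calibrated share-form CES. A node with elasticity
σ, share parameters δᵢ (benchmark expenditure shares), and taste
multipliers tᵢ has unit cost

    P = ( Σᵢ δ̃ᵢ pᵢ^(1-σ) )^(1/(1-σ)),   δ̃ᵢ = tᵢδᵢ / Σⱼ tⱼδⱼ

and cost-minimizing demands qᵢ = δ̃ᵢ (P/pᵢ)^σ · E/P for expenditure E;
σ = 1 is the Cobb-Douglas limit and σ = 0 Leontief. Equilibrium stacks zero
profit, commodity and factor market clearing, income balance, export demand
Eᵢ = E⁰ᵢ (pᵢ/PFX)^(−ηᵢ), and a CPI numeraire; the external-balance
equation is dropped (Walras' law) and reported as a diagnostic. Scenario
shocks are taste-multiplier twists on the household food nest, exact at
benchmark prices: beef expenditure scales by 1−r and the freed expenditure
lands on the plant-based leaf (ALTP) or spreads proportionally over the
rest of the food bundle (BEEF10).

## Worked example

```r
library(foodcge)
sam   <- generate_sam(economy_template(seed = 0))
model <- build_model(sam)
res   <- run_scenario(model, "ALTP30")
res
#> <scenario_result> ALTP30 (r = 0.3, target plant_based)
#>   beef output -16.78%; GDP 0.003%; Walras -9.73e-13
```

A 30% replacement of beef expenditure by plant-based alternatives contracts
beef processing by 16.8% and cattle ranching by 15.2% — roughly half the
demand cut, because falling beef prices pull in export demand — while grain
(+2.9%) and oilseed (+6.0%) farming expand to supply the plant-based
ingredients, and the tiny plant-based sector grows ~10-fold:

```r
res$footprint
#>     dimension baseline  change pct_change
#>     water_km3       94   2.918      3.104
#>          n_kt    10067 297.936      2.960
#>          p_kt     1636  52.020      3.180
#>        ghg_mt      347 -18.540     -5.343
#>  cropland_kha       NA      NA         NA   (unavailable)
```

Agricultural greenhouse-gas emissions fall by 18.5 Mt CO₂eq/yr (−5.3%),
but blue water and fertiliser use *rise* ~3% with the expanding crop
sectors — the resource-reallocation effect that static accounting misses.
Head counts follow sector output: about 4.5 million fewer cattle, and a
slight increase in chickens and pigs (`res$animals`). Running `"BEEF10"`
instead sends the freed expenditure to other foods — including poultry and
pork — and rears tens of millions more chickens; `compare_scenarios()`
makes that contrast explicit.

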