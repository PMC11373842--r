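# foodprintr

Agricultural resource footprints and carrying capacity of diet patterns.

`foodprintr` is a biophysical simulation of a national food system for
researchers at the nutrition–sustainability interface. It converts a diet
pattern — daily servings of 22 food groups, either one per-capita vector
or a table of individual one-day dietary recalls — *backwards* through
the food chain: servings → foods (preference shares) → pre-waste mass
(loss/waste factors) → raw agricultural commodities (processing, dairy
limiting fraction, fat/oil blends) → livestock and aquaculture feed →
land by type (cultivated cropland, cropland pasture, permanent pasture) →
fertilizer nutrients (N, P₂O₅, K₂O, S), pesticides, and irrigation water —
and forward again to the fraction of a population a fixed land base could
feed that diet.

## The model in brief

Per food *i*, annual commodity mass (lb/person/yr) is

```
commodity_i = intake_i × serving_size_i / 454 × preference_i
              × loss_waste_i × processing_i × 365
```

with dairy pooled through the fluid-milk equivalent
`FM = max(Σ intake·fat/0.037, Σ intake·nonfat/0.086)` (the limiting dairy
fraction), fat products decomposed into constituent oils, aquatic food
split into farmed (agricultural) and wild fractions, and animal products
expanded through feed conversion coefficients (the aquaculture ration is
a 2×2 corn/soybean-meal solve against energy and crude-protein
requirements). Land per food and land type *l* is

```
land_il = (commodity_i − trade_balance_i / population) / yield_il
```

after an eight-step multiuse-crop ledger credits coproducts (corn oil and
gluten feed from sweetener milling, soybean meal from oil crushing,
lard/tallow from meat) so no acre is counted twice. A grazing-land
adjustment reallocates grazing onto cropland when the required
grazing-to-cropland ratio RR exceeds the available ratio RA, and carrying
capacity is the minimum of three land-constrained population-fed values
divided by the population size.

## Worked example

The package ships a deterministic toy food system (`MINI`: 13 foods, 11
groups, every mechanism exercised) whose end-to-end results are verified
against a hand-computed oracle worksheet in the test suite.

```r
library(foodprintr)
params <- make_mini_food_system()
diet   <- mini_reference_diet()
res    <- run_single(diet, params,
                     scenario_config(population_size = 1e5,
                                     trade_mode = "closed"))
print(res)
#> <footprint_result>
#>   trade: closed; population: 100000
#>   land use: 0.5473 acres/person/yr (0.2215 ha) | total 54730 acres
#>     cultivated 0.1408, forage 0.0451, grazing 0.3848 acres/person
#>   population fed: cultivated_cropland 269850, all_cropland 356967, all_productive_land 544491
#>   carrying capacity: 2.699
#>   amendments/person: N 10.9, P2O5 5.38, K2O 6.87, S 1.11, pesticides 0.26, irrigation 0.0663
#>   diet energy: 820 kcal/day
```

Reading this: the reference diet needs 0.55 acres per person per year,
70% of it grazing land for beef and dairy; the MINI land base could feed
this diet to about 2.7× the stated population of 100,000, with the binding
constraint being cultivated cropland (269,850 people); fertilizer and
pesticide totals are the per-acre application rates summed over the
food-by-commodity land grid.

Survey batches (two passes — the >3 SD resource outlier screen needs a
first pass of per-record results):

```r
survey <- make_synthetic_survey(fixture_spec(seed = 1, n = 500))
batch  <- run_batch(survey, params, scenario_config())
batch$summary        # survey-weighted means and quartiles per resource
batch$exclusions     # tally: age<1, unreliable, zero intake, outliers, kept
```

## Command line

```sh
foodprint fixture  --seed 1 --n 100 --out fx        # MINI params + survey
foodprint validate --params fx/params
foodprint run      --params fx/params --diet diet.tsv --trade closed --out out
foodprint batch    --params fx/params --survey fx/survey.tsv --out out
```

(`foodprint` is `inst/cli/foodprint`; equivalently
`Rscript -e 'foodprintr::foodprint_cli()' <args>`.) Outputs are delimited
tables: `summary.tsv`, `expanded.tsv` (per food × land type), and for
batches `totals.tsv` / `exclusions.tsv`. Units are imperial internally;
`--units si` converts at the report layer only.

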