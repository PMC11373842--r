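---
title: "foodprintr: model, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foodprintr: model, conventions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodprintr)
```

## The model

`foodprintr` estimates the agricultural resources embodied in a diet
pattern by running consumption backwards through the food system. The
chain is strictly staged, and every stage is a pure function of its
inputs and a validated parameter set:

1. **Diet → foods.** Daily servings of food groups are split across the
   individual foods of each group by *preference shares* (per-capita
   availability proportions). Foods that cannot be produced in the study
   area have their share reapportioned to the producible foods of the
   same group, in proportion to those foods' own shares; the raw shares
   are retained for provenance.
2. **Foods → commodity mass.** Per food:
   `servings × grams-per-serving / 454 × loss_waste × processing × 365`,
   giving lb of raw commodity per person per year. The loss/waste factor
   is a single multiplier (retail loss × inedible fraction × cooking loss
   × consumer waste, pre-combined); the four-factor decomposition is a
   property of the source data, not of the computation.
3. **Dairy.** All dairy foods are pooled into a fluid-milk equivalent:
   `FM_fat = Σ intake·fat/0.037`, `FM_nonfat = Σ intake·nonfat/0.086`,
   `FM = max(FM_fat, FM_nonfat)`. The constants are the fat and non-fat
   solids proportions of fluid milk itself, so a pure-fluid-milk diet
   maps to exactly its own mass. The max() picks the *limiting dairy
   fraction*; the non-limiting fraction's surplus is discarded rather
   than credited elsewhere, mirroring the worksheet semantics this model
   descends from. Butter-like "dairy fats" are routed through the dairy
   compositions, not the vegetable-oil path.
4. **Fats and oils.** Processed fat products (cooking oil, shortening,
   …) decompose into constituent oils by mass share (shares sum to 1;
   mass conserved). Oil mass converts to oilseed mass at the land stage
   via crush coefficients (lb seed per lb oil).
5. **Animals.** Animal-product demand expands into feed (lb corn grain,
   corn silage, soybean meal, hay, haylage, grazed forage per lb
   product). These coefficients are *inputs* — they come from an
   upstream livestock ration model and are not re-derived here. Farmed
   aquatic demand is expanded through a two-ingredient nutritional
   solve: feed per edible lb = FCR / processing efficiency; multiplying
   by the ration's energy and protein densities gives requirements met
   exactly by a corn/soybean-meal blend (2×2 linear solve; infeasible
   exact blends clip to the cheapest nonnegative single-ingredient
   ration with a warning). Wild-caught aquatic food is carried but
   flagged non-agricultural and claims no resources.
6. **Trade.** Open systems credit each food's balance
   (`stock + imports − exports`, per capita) against demand; closed
   systems ignore trade entirely. Zero trade records make open and
   closed runs bit-identical, which the property suite asserts.
7. **Multiuse crops.** An eight-step ledger credits coproducts so land
   is not double counted (below).
8. **Land, capacity, amendments.** Net commodity mass divides by the
   commodity's primary-land-type yield; availability formulas,
   grazing reallocation, three population-fed constraints, carrying
   capacity, total land use, and per-acre amendment rates complete the
   accounting.

Internal units are those of the source accounting — lb, acres,
servings/day, lb/acre — because the mass equation hard-codes 454 g/lb
and 365 d/yr. SI conversion (acres × 0.404686 → ha, lb × 0.453592 → kg,
irrigation acre-feet × 1233.48 → m³) happens only in the report layer.

## The multiuse-crop ledger

The source describes the eight steps verbally; the concrete arithmetic
(each step a sum, min, or zero-floored difference) is fixed here and
every intermediate is exposed on the returned object for audit:

1. Corn milled for sweetener demand coproduces corn oil
   (`corn × corn_oil_per_lb_corn`) and gluten-feed protein
   (`corn × gluten_feed_per_lb_corn × gluten_feed_protein`).
2. Oil demand per oilseed and crush coefficients are collected.
3. Protein meal coproduced from crushing, and lard/tallow coproduced
   from animal foods (`Σ product × fat rate`), are tabulated.
4. Corn oil spared = `min(corn oil consumed, corn oil coproduced)`;
   corn spared = spared oil × lb corn per lb oil.
5. Lard/tallow remaining = `max(0, demand − coproduced)`. Remaining
   demand claims **no** land: animal fat is a coproduct of animals the
   model already counts. The surplus (`max(0, coproduced − demand)`)
   joins the fat pool.
6. The surplus fat pool (surplus corn oil + surplus lard/tallow)
   offsets oilseed-oil demand, allocated proportionally across
   oilseeds; the spared seed mass is credited per seed crop.
7. Feed protein coproduced from crushing is computed on the oilseed
   mass *actually* crushed (post-offset). This resolves an overlap
   between steps 3 and 7 in the verbal description: crediting
   pre-offset protein would count meal from seeds that are never
   crushed.
8. Soybeans spared from the feed ration =
   `(gluten protein + crush protein) / (meal yield × meal protein)`,
   capped at the soybean mass the feed ration demands.

Offsets are applied as commodity-mass reductions *before* the division
by yield — at fixed yield this is identical to a land offset, and it
lets the crop and fat/oil land equations share one code path. All
offsets are proportional within a commodity and floored so net demand
never goes negative; consequently the adjustment can never increase any
commodity's land, which the property suite checks on randomized systems.

## Grazing reallocation and the RY convention

With `RA = available grazing / available cropland` and
`RR = Σ grazing land / Σ(cultivated/CI + forage land)`, reallocation
fires when `RR > RA`:
`cropland_used_for_grazing = (ΣG − RA·Σ(C/CI + F)) / (RA + RY)`,
`grazing_land_offset = cropland_used_for_grazing × RY`.

The printed convention defines `RY = Yield_g / Yield_p` (grazing-land
yield over cropland grazing yield). Under that convention the forage
mass balance — forage harvested on the reallocated cropland
(`CUG × Yield_p`) equalling the forage forgone on released pasture
(`offset × Yield_g`) — does **not** hold algebraically: it requires the
inverse ratio, since one cropland acre at higher yield replaces
`Yield_p / Yield_g` pasture acres. Both conventions are implemented
(`ry_convention = "as_printed"`, the default, reproduces the worked
example `CUG = 32, offset = 16` on the MINI numbers;
`"mass_balance"` satisfies the exact balance, which the property test
asserts). Which availability enters RA is also not pinned down by the
source; the default is food cropland for all uses, configurable to
cultivated-only.

Two further printed-form ambiguities are resolved the same way —
faithful default, alternative exposed:

* **Trade sign.** The printed balance sums exports with a plus sign;
  the surrounding narrative (exports ⇒ more production needed) requires
  a minus. Default subtracts (`sign = "narrative"`); the printed form
  is `sign = "printed"`.
* **Aquaculture dimensional form.** The printed requirement multiplies
  FCR by processing efficiency; the stated definitions (FCR = feed per
  live-weight gain; efficiency = edible per live mass) require
  division, and multiplication *understates* feed whenever efficiency
  < 1. Default divides; `strict_paper_aquaculture = TRUE` reproduces
  the printed product.
* **Total land use.** The printed expression contains unparseable
  groupings; it is read as
  `cultivated/CI + (forage + CUG) + (grazing − offset)`, the only
  reading consistent with the reallocation's bookkeeping; with a zero
  adjustment it reduces to the plain sum.

## Diet input and exclusions

A diet is servings/day over a configurable group list; the canonical
22-group schema (`food_groups_22`) adds `fruit` to the 21 groups the
source enumerates, since the fruit category is plainly modelled.
Individual records carry id, age, survey weight, and a reliability
flag; conversion from raw recall foods to food-pattern-equivalent
servings is an upstream contract, not performed here. Exclusions apply
in order: age < 1 year; unreliable recall; zero intake of every
modelled group; then a single-pass unweighted >3 SD screen on land,
summed fertilizer nutrients, and pesticides (irrigation deliberately
not screened). The screen needs per-record results, so batch runs are
two-pass. Records are one-day recalls: no usual-intake modelling.

The nutrient summary uses the reapportioned preference shares — it
describes the diet the land model serves, and within a food group the
compositional differences this introduces are second-order next to the
serving-size heterogeneity the shares already average over.

## Synthetic data

`make_mini_food_system()` is a deterministic 13-food system whose
values are chosen for hand arithmetic: bread at 28 g/oz-eq with wheat
at 2700 lb/acre; cheese at 0.30/0.25 solids; an aquaculture ration
whose 2×2 solve lands exactly on (1, 1); grazing yields 2000/4000 so
RY is exactly 0.5; a non-producible vegetable exercising
reapportionment. The independent oracle — straight-line literal
arithmetic, no package code — lives in
`tests/testthat/helper-oracle.R`, and the acceptance suite requires
agreement to 1e-9 relative on every intermediate.

`make_synthetic_survey()` draws zero-inflated log-normal intakes
(dietary intake is right-skewed, and many respondents report zero
intake of a group on any one day), uniform ages 1–85, log-normal
survey weights, and a configurable fraction of extreme beef consumers
(default 5% at 5 servings/day) so that individual diets can trigger
grazing reallocation that the population-mean diet does not. Default
group means are the MINI reference diet; the log-normal meanlog is set
so the unconditional mean matches the target. What it does *not*
emulate: multistage sample designs (weights are i.i.d. noise),
intra-individual day-to-day variance, age- or sex-dependent intake
structure, or any quantitative match to national survey marginals. A
green test therefore establishes mechanical correctness of the
pipeline and the direction of the individual-vs-population grazing
effect, not calibration to any real population.

One structural fact worth knowing: RR is scale-free, so whether a diet
triggers reallocation depends on its food-group *mix*, not its amount.
Any beef-dominated record triggers; cohorts meant to stay below RA
must keep per-record mixes near the reference mix (the no-trigger
branch of the acceptance suite uses `sdlog = 0.1` and no zero
inflation for exactly this reason).

## Numerical choices

* Validation is total and collected: every declared invariant on every
  table is checked at load/construction and all violations reported
  together. Share closures use a 1e-9 tolerance.
* Serialization writes numerics with 17 significant digits; load/write
  round trips are type- and value-identical, enforced by test.
* Degenerate guards: demand with no primary yield is fatal (silent
  drops underestimate land); negative availability floors to 0 with a
  warning; zero per-capita requirements report `Inf` population fed;
  commodities without amendment rates contribute 0 with a warning
  (totals are conservative).
* Trade credits and multiuse offsets are allocated proportionally
  across a food's (respectively commodity's) demand rows, then floored
  at zero.
* The 3-SD screen is a single pass (no iteration) with unweighted
  moments over the post-demographic-screen sample.

## Limitations

No uncertainty propagation through the parameter tables; no spatial or
seasonal disaggregation of yields or preferences; no least-cost ration
optimization beyond the two-ingredient aquaculture solve; no
micronutrient constraints; no diet-quality scoring or regression
analysis (the batch output is designed to be consumed by external
statistical tooling); the deposited-workbook importer is out of scope,
so parameter sets enter through the delimited-table format documented
in `?food_system_parameters`.
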