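---
title: "Comparing nutrient profile models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nutrient profile models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmagree)
```

`npmagree` measures how much nutrient profile models (NPMs) proposed for
regulating broadcast food advertising to children agree about which
foods may be advertised. This vignette is the package's account of the
underlying methods: the model engine, the dataset-assembly conventions,
the agreement statistics, the synthetic-data generator, and the design
decisions taken where the published record is silent.

## The model engine

An NPM is a declarative YAML configuration in one of two modes.

**Threshold mode.** A model is an ordered list of category rules. Each
rule has a predicate over the food record (tag membership and/or the
drink flag) plus a rank; rules are tried in rank order and the *first*
match wins, so a food fitting several categories is resolved
deterministically. Every model must end with a catch-all rule: category
assignment is total by construction. The first-match-by-priority
convention is our choice — published model descriptions rarely state a
tie-break — and it keeps classification auditable: the matched rule and
every criterion evaluation are recorded in the result.

Each category carries criteria of the form *nutrient, basis, comparator,
threshold*. Bases are `per_100g` (equivalently `per_100ml` for drinks at
density 1), `per_serving` (value × serving/100), `per_100kcal`, and
`pct_energy` (using 9 kcal/g for fats, 4 for sugars and protein, 2 for
fibre; kcal is derived from kJ at 4.184 kJ/kcal when absent).
Comparators are applied exactly: a sodium value of exactly 300 passes a
`<= 300` criterion, and no rounding is applied to observed values before
comparison — rounding rules would silently change classifications near
thresholds, so rounding exists only at report time (half-up, 1–2
decimals).

**Points mode** (the UK FSA/Ofcom model). Components map to ordered
*(strict lower bound, points)* pairs: a value earns the points of the
highest bound it exceeds, so a value sitting exactly on a bound earns
the lower score. A-points (energy kJ, saturated fat, total sugar,
sodium; capped at 10 each) and C-points (fruit/veg/nuts with attainable
points 1, 2, 5; fibre; protein, each up to 5) combine as
`score = A − C`, with protein credited only while `A < 11` or
fruit/veg/nuts scores 5. Foods are approved below a score of 4, drinks
below 1. Fibre has two threshold columns because the NSP (Englyst) and
AOAC assays measure different quantities; each food carries a
`fibre_method` flag selecting the column, defaulting to NSP.

**Missing data are a hard error.** The engine never treats an absent
nutrient as an implicit pass or fail; classification demands a food
complete for the model's nutrient set, which is exactly the discipline
the assembly stage's supplementation step enforces.

**Incomplete models.** Eight model configurations ship with the package.
Only the UK FSA/Ofcom points table and the Brazilian ANVISA thresholds
(total sugar 15 g, saturated fat 5 g, trans fat 0.6 g, sodium 400 mg per
100 g for foods; 7.5 / 2.5 / 0.3 g and 200 mg per 100 ml for drinks)
could be transcribed from official public documentation. The Danish,
Disney, PepsiCo, US CSPI, US Interagency and EU Pledge files carry the
documented *structure* — nutrient sets and category counts (10, 17, 7,
6, 2 and 20 respectively) — but their numeric thresholds are marked
`TODO` rather than guessed; the two published EU Pledge sodium values
(≤300 mg/100 g for milk and milk substitutes, ≤450 mg/100 g for
breakfast cereals) are the exception and are encoded. An incomplete
model supports registry introspection but refuses to classify, and
default pipeline runs exclude it with a logged notice. Category
identifiers inside the incomplete files are synthetic placeholders; only
their count is documented. One tally quirk is preserved deliberately:
the PepsiCo row of the published comparison marks ten nutrient columns
but prints a total of nine; the config encodes the ten marked
components.

**The Danish sodium question.** The Danish model lists a sodium
criterion only as a "further consideration" and it is genuinely unclear
when it applies. It is therefore modelled as an *optional* criterion
gated by the model option `danish_sodium_considered`, default off.
Because adding a criterion can only flip results from approved to
not-approved, enabling the option is monotone restrictive — a property
the test suite checks. Registry introspection consequently counts seven
sodium-using models by default and eight when optional criteria are
included.

## Dataset assembly

The assembly operations mirror how an advertised-food dataset is built
from a broadcast sample:

- **Exclusions** remove four classes of commercials (alcohol/tea/coffee/
  chewing gum; broad-range retailers; baby and toddler foods;
  weight-loss/-gain shakes). The classes are explicit input *tags*, not
  inferred from names: whether an advertiser is a "broad-range retailer"
  is a human judgement, and keeping it an input makes the rule
  mechanical, order-independent and auditable. Unknown tags are fatal.
- **Brand representatives**: a brand sold as a range is represented by
  one product drawn uniformly with an explicit seed, so the draw is
  reproducible and recorded.
- **Meal averaging**: meal components (drinks included) combine as a
  serving-mass-weighted mean per 100 g; drink millilitres are treated as
  grams (density 1), a convention the published record does not state.
  A nutrient present in only some components is an error unless the
  caller selects the zero-fill policy, again to avoid silent data
  invention.
- **Supplementation**: branded values always take precedence; only
  absent fields are filled from a generic composition-table entry, the
  record's provenance flips to "mixed", and a field absent in both
  sources is an error. Supplementation is idempotent.
- **Validity correlation**: for nutrients with both branded and generic
  values, the package reports the Pearson r (computed on per-100 g
  values without transformation) and the least-squares slope of generic
  on branded, which expresses whether the generic table over- or
  under-estimates. Zero-variance series are reported as degenerate
  rather than silently yielding NaN.

## Agreement statistics

**Approval proportions.** Each model's approval is summarised at two
levels: percent of distinct foods, and percent of commercials (foods
weighted by broadcast counts). Both carry a 95% normal-approximation
binomial interval whose half-width uses the *number of foods* as n —
repeated broadcasts of one commercial are not independent
classifications, so they contribute no variance. Applying that same
food-based half-width to the commercial-level point estimate is a
reconstruction choice: the acceptance tests verify that it reproduces
all sixteen published interval pairs to within the precision of the
printed inputs. Intervals are clipped to [0, 100].

**Cohen's kappa.** Pairwise agreement uses the weighted 2×2 contingency
table in which each food contributes its commercial count as a frequency
weight; `kappa = (p_o − p_e)/(1 − p_e)`. Perfect agreement returns
exactly 1 (avoiding 0/0), and degenerate marginals with imperfect
agreement return NA flagged as undefined. No bias or prevalence
correction is applied. Interpretation bands follow the conventional cut
points — 0.21–0.40 "fair", 0.41–0.60 "moderate", 0.61–0.80 "good" —
with values below 0.21 labelled "less than fair" and above 0.80 "very
good". A boundary value belongs to the band whose printed range names it
(0.40 is "fair"); the published ranges touch without stating ownership,
so this is recorded as our convention.

**Breakdowns and counts.** Category breakdowns report percent of
commercials approved per food-guide group (the seven UK "Balance of Good
Health" groups, with fatty/sugary split into snacks, non-snacks and
drinks); a category with zero commercials is undefined, not zero. The
per-food approving-model count (0 to the number of models) summarises
consensus; its distribution is reported with commercial weights, and the
weighted share at count 0 measures how much advertising *every* model
would bar.

## The synthetic-data generator

No advertised-food dataset with broadcast counts is publicly available,
so the generator emulates one: by default 336 foods whose food-guide
category mix follows the published proportions (51 bread/cereals, 80
composite, 125 fatty/sugary split 91/14/20, 10 fruit/veg, 15 meat/fish,
41 milk/dairy, 14 miscellaneous), with 11 763 commercials in total.
Broadcast counts are heavy-tailed: drawn log-normal (meanlog 2.5, sdlog
1.3), floored at 1, and rescaled to the exact target total. Nutrient
marginals are truncated log-normals per category with parameters in the
shipped fixture `extdata/nutrient_distributions.csv`; no distributional
information was published, so parameters were chosen once for
non-negativity, realistic right skew and — the property that matters for
testing — spanning the pass/fail boundaries of the shipped models.
Physical consistency is enforced after the draw (saturated and trans fat
capped by total fat, added by total sugar, energy kcal = kJ/4.184).
Three archetype foods are injected verbatim: bottled water (approved by
every model), garden peas (approved), and a chocolate confectionery
(rejected). Identical seeds give byte-identical CSV output.

`generate_with_ground_truth()` plants per-model approval rates: each
food draws target flags from the planted rates, then rejection-samples
nutrient vectors from a mixture of proposal pools (strongly healthy,
strongly unhealthy, and contrast archetypes such as
salty-but-otherwise-healthy and energy-dense-plain) until the *engine's
own classification* matches every target. The recorded truth is always
the engine's verdict, so empirical rates are binomially distributed
around the planted ones; jointly unsatisfiable targets exhaust the
sampling budget and fail loudly.

The generator emulates marginal structure only. It does not reproduce
the joint nutrient distribution of real advertised foods, real brands,
or the correlation between nutritional quality and broadcast frequency.
Passing tests on synthetic data therefore demonstrate that the
*machinery* (engine, statistics, pipeline) is correct and internally
consistent, not that any synthetic approval percentage or kappa estimates
its real-data counterpart.

## Numerical choices and problem sizes

- Thresholds and points bounds compare exact values; no internal
  rounding anywhere. Report rounding is half-up, at output only.
- Confidence intervals use z = 1.96; the degenerate all-approved case
  yields a zero-width interval at 100%.
- The test suite sizes its simulations for depth without waste: oracle
  equivalence runs 1 000 random foods against a naive evaluator that
  re-reads the YAML configs; points-scorer monotonicity runs 10 000
  random perturbations; CI coverage uses 2 000 replicates at n = 336;
  planted-rate recovery uses the emulated dataset size (336). These
  sizes give 3-sigma-level sensitivity for the properties checked.
- All randomness is seeded; brand selection and generation restore the
  caller's RNG state.

## Limitations

- Six of the eight shipped model configurations await threshold
  transcription from their primary documentation and cannot classify
  until completed; all agreement analyses over the default registry
  therefore compare the UK and Brazilian models only.
- Meal averaging dilutes nutrient density when drinks are included;
  regulators assessing each component separately would classify some
  meals differently. This mirrors the assembly convention the package
  models and is inherent to averaging.
- The kappa weighting treats commercial counts as exact frequency
  weights in both margins; other weighting readings of "weighted by
  number of commercials" are conceivable but are not implemented.
- The synthetic generator's distribution parameters are fixed design
  constants, not fitted quantities; they are not a basis for empirical
  claims about real advertising.
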