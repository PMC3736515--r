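# npmagree

Agreement between nutrient profile models for regulating broadcast food
advertising to children.

## The problem

Nutrient profile models (NPMs) classify foods by nutritional composition
to decide which ones may be advertised to children. Several such models
exist — developed by government agencies (the UK FSA/Ofcom model, the
proposed Brazilian ANVISA criteria, the US Interagency Working Group
principles), industry (PepsiCo, EU Pledge), consumer groups (US CSPI),
and others (Danish Forum code, Disney guidelines) — and they disagree:
applied to the same advertised foods they can permit anywhere from a few
percent to nearly half of commercials. `npmagree` is a toolkit for
quantifying that disagreement. It provides:

- a **declarative model engine**: NPMs are YAML configurations, either
  priority-ordered category rules with nutrient threshold criteria, or an
  FSA/Ofcom-style points table; foods are classified with a full
  per-criterion audit trail;
- the **dataset-assembly stage** used to build advertised-food datasets:
  mechanical exclusion rules, seeded random brand representatives,
  serving-mass-weighted meal averaging, supplementation of branded
  nutrition panels from a generic composition table, and the
  branded-vs-generic Pearson validity check;
- the **agreement statistics**: commercial-weighted approval proportions
  with food-based binomial confidence intervals, pairwise Cohen's kappa
  on commercial-weighted 2×2 tables with banded interpretation,
  food-guide category breakdowns, and per-food approving-model counts;
- a **seeded synthetic-data generator** that emulates the shape of a UK
  2008 advertised-food dataset (336 foods, 11 763 commercials,
  heavy-tailed broadcast counts) so the whole pipeline is testable
  without proprietary data.

## The statistics

For one model over `n` foods with approval flags `x_i` and broadcast
counts `w_i`:

- foods approved: `p_f = mean(x_i)`; commercials approved:
  `p_c = sum(w_i x_i) / sum(w_i)`;
- both carry a normal-approximation binomial 95% CI with half-width
  `1.96 * sqrt(p_f (1 - p_f) / n)` based on the **number of foods** —
  repeated broadcasts of one commercial add no independent
  classification information;
- pairwise agreement is Cohen's `kappa = (p_o - p_e) / (1 - p_e)` on the
  2×2 table in which each food contributes its commercial count as a
  frequency weight, read against the conventional bands (0.21–0.40
  "fair", 0.41–0.60 "moderate", 0.61–0.80 "good").

In the UK FSA/Ofcom scoring model, "A" points accrue for energy,
saturated fat, total sugar and sodium and "C" points for fruit/veg/nuts,
fibre and protein (protein only while A < 11 or fruit/veg/nuts = 5
points); a food is "less healthy" — barred from advertising — when
`score = A - C` reaches 4 (drinks: 1).

Model configurations whose published thresholds have not been
transcribed ship as structure-only files (criteria marked `TODO`); they
support registry introspection but are excluded from classification runs
until completed. The UK and Brazilian models ship complete.

## Worked example

```r
library(npmagree)

registry <- load_model_registry()
registry_summary(registry)[, 1:5]
#>                      model_id      mode n_categories complete n_nutrients
#> brazilian           brazilian threshold            2     TRUE           4
#> danish                 danish threshold           10    FALSE           3
#> disney                 disney threshold           17    FALSE           6
#> eu_pledge           eu_pledge threshold           20    FALSE           9
#> pepsico               pepsico threshold            7    FALSE          10
#> uk                         uk    points            2     TRUE           7
#> us_cspi               us_cspi threshold            6    FALSE           4
#> us_interagency us_interagency threshold            2    FALSE           5

peas <- food_record("peas", name = "garden peas",
  nutrients = nutrient_composition(energy_kJ = 290, saturated_fat_g = 0.2,
    total_sugar_g = 2.3, sodium_mg = 1, protein_g = 5.4, fibre_g = 4.5,
    fruit_veg_nut_pct = 100, total_fat_g = 0.9, trans_fat_g = 0),
  food_guide_category = "fruit_veg", serving_size_g = 80)
classify(peas, registry$uk)
#> <classification_result> peas x uk: APPROVED (category food, score -13)
```

Peas earn no A-points and the maximum C-points, so their score of −13
sits far below the fail threshold of 4. A full synthetic comparison run:

```r
res <- run_pipeline(run_config(seed = 1))
res$approval_table
#>            model_id n_foods_approved pct_foods_approved pct_foods_ci_lo ...
#> brazilian brazilian              100               29.8            24.9
#> uk               uk               97               28.9            24.0
res$kappa
#> <agreement_matrix> pairwise Cohen's kappa, commercial counts as frequency weights
#>           brazilian   uk
#> brazilian      1.00 0.63
#> uk             0.63 1.00
res$model_counts$pct_commercials_none
#> [1] 61.1
```

On this seed the two complete models approve ~29–34% of commercials each
and agree at κ = 0.63; 61% of synthetic commercials are rejected by
both. Setting `out_dir` in `run_config()` writes the per-model approval
table, the kappa matrix with band stars, the per-category breakdown and
a per-food audit CSV; identical seeds reproduce the files byte for byte.
A thin command-line wrapper with `simulate`, `classify`, `compare`,
`report` and `run` subcommands is installed at
`system.file("cli", "npmagree", package = "npmagree")`.

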