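# PepsiCo Global Nutrition Criteria for Advertising to Children:
# seven product categories; criteria drawing on calories, added sugar,
# total/saturated/trans fat, cholesterol, sodium, protein, fibre and
# qualifying micronutrients. (The published comparison's nutrient tally
# prints 9 for this model while marking 10 nutrient columns; the 10
# marked components are encoded here.)
#
# STATUS: INCOMPLETE. Thresholds TODO; excluded from default runs.
# Category ids are synthetic placeholders carrying the documented
# category count (7).
model_id: pepsico
name: PepsiCo advertising-to-children criteria
mode: threshold
categories:
  - {category_id: beverages, priority: 1, match: {is_drink: true},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: savoury_snacks, priority: 2, match: {tags_any: [snack]},
     criteria: [{nutrient: total_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: breakfast_cereals, priority: 3, match: {tags_any: [breakfast_cereal]},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: fibre_g, basis: per_serving, comparator: ">=", threshold: TODO}]}
  - {category_id: dairy_products, priority: 4, match: {tags_any: [milk]},
     criteria: [{nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: protein_g, basis: per_serving, comparator: ">=", threshold: TODO}]}
  - {category_id: grain_products, priority: 5, match: {tags_any: [bread]},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: meal_products, priority: 6, match: {tags_any: [meal, composite]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: cholesterol_mg, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: micronutrient_count, basis: per_serving, comparator: ">=", threshold: TODO}]}
  - {category_id: other_foods, priority: 7, match: {catch_all: true},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: total_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: cholesterol_mg, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
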