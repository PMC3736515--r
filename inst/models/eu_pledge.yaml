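# EU Pledge Nutrition Criteria: 20 product categories with
# category-specific limits over energy, total sugar, fat, saturated fat,
# sodium, protein, fibre, fruit/veg and qualifying micronutrients.
#
# STATUS: INCOMPLETE. The only numeric limits carried here are the two
# published sodium thresholds: <= 300 mg/100 g for milk and milk
# substitutes and <= 450 mg/100 g for breakfast cereals. All other
# thresholds are TODO pending transcription from the EU Pledge criteria
# document, so the model is excluded from default classification runs.
# Category ids beyond the two documented ones are synthetic placeholders
# carrying the documented category count (20).
model_id: eu_pledge
name: EU Pledge Nutrition Criteria
mode: threshold
categories:
  - {category_id: vegetable_oils_and_fats, priority: 1, match: {tags_any: [oil_fat]},
     criteria: [{nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: fruit_vegetable_seed_products, priority: 2, match: {tags_any: [fruit_veg]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: meat_products, priority: 3, match: {tags_any: [meat_fish_alternatives]},
     criteria: [{nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: fishery_products, priority: 4, match: {tags_any: [fish]},
     criteria: [{nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: milk_and_milk_substitutes, priority: 5, match: {tags_any: [milk]},
     criteria: [{nutrient: total_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: 300}]}
  - {category_id: yoghurts_fermented_milks, priority: 6, match: {tags_any: [yoghurt]},
     criteria: [{nutrient: total_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: cheese_products, priority: 7, match: {tags_any: [cheese]},
     criteria: [{nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO},
                {nutrient: protein_g, basis: per_100kcal, comparator: ">=", threshold: TODO}]}
  - {category_id: bread_products, priority: 8, match: {tags_any: [bread]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO},
                {nutrient: fibre_g, comparator: ">=", threshold: TODO}]}
  - {category_id: breakfast_cereals, priority: 9, match: {tags_any: [breakfast_cereal]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: 450},
                {nutrient: fibre_g, comparator: ">=", threshold: TODO}]}
  - {category_id: pasta_rice_grains, priority: 10, match: {tags_any: [grain]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: soups, priority: 11, match: {tags_any: [soup]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: composite_dishes, priority: 12, match: {tags_any: [composite]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: main_meals, priority: 13, match: {tags_any: [meal]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: fruit_veg_nut_pct, comparator: ">=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: savoury_snacks, priority: 14, match: {tags_any: [snack]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO}]}
  - {category_id: fine_bakery_wares, priority: 15, match: {tags_any: [bakery]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, comparator: "<=", threshold: TODO}]}
  - {category_id: desserts, priority: 16, match: {tags_any: [dessert]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: ice_creams, priority: 17, match: {tags_any: [ice_cream]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, comparator: "<=", threshold: TODO}]}
  - {category_id: beverages, priority: 18, match: {is_drink: true},
     criteria: [{nutrient: energy_kcal, comparator: "<=", threshold: TODO},
                {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: cereal_bars, priority: 19, match: {tags_any: [cereal_bar]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: micronutrient_count, comparator: ">=", threshold: TODO}]}
  - {category_id: not_covered, priority: 20, match: {catch_all: true},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: total_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, comparator: "<=", threshold: TODO},
                {nutrient: protein_g, basis: per_100kcal, comparator: ">=", threshold: TODO},
                {nutrient: fibre_g, comparator: ">=", threshold: TODO},
                {nutrient: fruit_veg_nut_pct, comparator: ">=", threshold: TODO},
                {nutrient: micronutrient_count, comparator: ">=", threshold: TODO}]}
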