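# Disney nutrition guidelines: 17 food categories with limits on
# calories, added and total sugar, saturated fat, trans fat and sodium.
#
# STATUS: INCOMPLETE. Thresholds are TODO pending transcription from the
# model's own documentation; excluded from default classification runs.
# Category ids are synthetic placeholders carrying the documented
# category count (17).
model_id: disney
name: Disney nutrition guidelines
mode: threshold
categories:
  - {category_id: complete_meals, priority: 1, match: {tags_any: [meal]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: mini_meals, priority: 2, match: {tags_any: [mini_meal]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: beverages, priority: 3, match: {is_drink: true},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: juices, priority: 4, match: {tags_any: [juice]},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: milk_products, priority: 5, match: {tags_any: [milk]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO}]}
  - {category_id: yoghurt, priority: 6, match: {tags_any: [yoghurt]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: cheese, priority: 7, match: {tags_any: [cheese]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: breads_grains, priority: 8, match: {tags_any: [bread]},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: breakfast_cereals, priority: 9, match: {tags_any: [breakfast_cereal]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: soups, priority: 10, match: {tags_any: [soup]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: fruits, priority: 11, match: {tags_any: [fruit]},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: vegetables, priority: 12, match: {tags_any: [vegetable]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: meats_proteins, priority: 13, match: {tags_any: [meat_fish_alternatives]},
     criteria: [{nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, comparator: "<=", threshold: TODO}]}
  - {category_id: snacks, priority: 14, match: {tags_any: [snack]},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: frozen_desserts, priority: 15, match: {tags_any: [dessert]},
     criteria: [{nutrient: total_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: condiments, priority: 16, match: {tags_any: [condiment]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: other_foods, priority: 17, match: {catch_all: true},
     criteria: [{nutrient: energy_kcal, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: total_sugar_g, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
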