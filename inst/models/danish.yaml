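# Danish model (Forum of Responsible Food Marketing Communication).
# Ten food categories with limits on total sugar and fat, plus a sodium
# criterion listed only as a "further consideration"; it is unclear when
# that sodium criterion applies, so it is modelled as an optional
# criterion gated by the option `danish_sodium_considered` (default off).
#
# STATUS: INCOMPLETE. The numeric limits are published in the model's own
# documentation, which is not reproduced here; thresholds are marked TODO
# and the model is excluded from default classification runs until they
# are transcribed. Category ids are synthetic placeholders carrying only
# the documented category count (10).
model_id: danish
name: Danish Forum code nutrient criteria
mode: threshold
options:
  danish_sodium_considered: false
categories:
  - category_id: breakfast_cereals
    priority: 1
    match: {tags_any: [breakfast_cereal]}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
      - {nutrient: sodium_mg, comparator: "<=", threshold: TODO,
         optional: true, option: danish_sodium_considered}
  - category_id: bread_products
    priority: 2
    match: {tags_any: [bread]}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: dairy_products
    priority: 3
    match: {tags_any: [milk]}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: cheese
    priority: 4
    match: {tags_any: [cheese]}
    criteria:
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: meat_products
    priority: 5
    match: {tags_any: [meat_fish_alternatives]}
    criteria:
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
      - {nutrient: sodium_mg, comparator: "<=", threshold: TODO,
         optional: true, option: danish_sodium_considered}
  - category_id: ready_meals
    priority: 6
    match: {tags_any: [composite]}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: savoury_snacks
    priority: 7
    match: {tags_any: [snack]}
    criteria:
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: confectionery
    priority: 8
    match: {tags_any: [confectionery]}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
  - category_id: beverages
    priority: 9
    match: {is_drink: true}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
  - category_id: other_foods
    priority: 10
    match: {catch_all: true}
    criteria:
      - {nutrient: total_sugar_g, comparator: "<=", threshold: TODO}
      - {nutrient: total_fat_g, comparator: "<=", threshold: TODO}
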