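# US CSPI (Center for Science in the Public Interest) guidelines for
# responsible food marketing to children: six categories with limits on
# added sugar, fat, trans fat and sodium.
#
# STATUS: INCOMPLETE. Thresholds TODO; excluded from default runs.
# Category ids are synthetic placeholders carrying the documented
# category count (6).
model_id: us_cspi
name: US CSPI marketing-to-children guidelines
mode: threshold
categories:
  - {category_id: beverages, priority: 1, match: {is_drink: true},
     criteria: [{nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: dairy_products, priority: 2, match: {tags_any: [milk]},
     criteria: [{nutrient: total_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: added_sugar_g, comparator: "<=", threshold: TODO}]}
  - {category_id: snacks, priority: 3, match: {tags_any: [snack]},
     criteria: [{nutrient: added_sugar_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: total_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: main_dishes, priority: 4, match: {tags_any: [composite]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: meals, priority: 5, match: {tags_any: [meal]},
     criteria: [{nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
  - {category_id: other_foods, priority: 6, match: {catch_all: true},
     criteria: [{nutrient: added_sugar_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: total_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO}]}
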