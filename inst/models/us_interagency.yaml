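# US Interagency Working Group proposed principles: two categories
# (individual foods; main dishes and meals) with per-serving limits on
# added sugar, saturated fat, trans fat and sodium plus a required
# contribution from food groups (represented by fruit/veg/nuts content).
#
# STATUS: INCOMPLETE. Thresholds TODO; excluded from default runs.
model_id: us_interagency
name: US Interagency Working Group principles
mode: threshold
categories:
  - {category_id: main_dishes_and_meals, priority: 1, match: {tags_any: [meal, composite]},
     criteria: [{nutrient: added_sugar_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: fruit_veg_nut_pct, comparator: ">=", threshold: TODO}]}
  - {category_id: individual_foods, priority: 2, match: {catch_all: true},
     criteria: [{nutrient: added_sugar_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: saturated_fat_g, basis: pct_energy, comparator: "<=", threshold: TODO},
                {nutrient: trans_fat_g, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: sodium_mg, basis: per_serving, comparator: "<=", threshold: TODO},
                {nutrient: fruit_veg_nut_pct, comparator: ">=", threshold: TODO}]}
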