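# Brazilian model (ANVISA resolution RDC 24/2010): foods are barred from
# advertising to children when they exceed any of four per-100 g (solids)
# or per-100 ml (drinks) limits on total sugar, saturated fat, trans fat
# and sodium. Two categories: foods and drinks.
model_id: brazilian
name: Brazilian ANVISA advertising-restriction criteria
mode: threshold
categories:
  - category_id: drinks
    priority: 1
    match:
      is_drink: true
    criteria:
      - {nutrient: total_sugar_g, basis: per_100ml, comparator: "<=", threshold: 7.5}
      - {nutrient: saturated_fat_g, basis: per_100ml, comparator: "<=", threshold: 2.5}
      - {nutrient: trans_fat_g, basis: per_100ml, comparator: "<=", threshold: 0.3}
      - {nutrient: sodium_mg, basis: per_100ml, comparator: "<=", threshold: 200}
  - category_id: foods
    priority: 2
    match:
      catch_all: true
    criteria:
      - {nutrient: total_sugar_g, basis: per_100g, comparator: "<=", threshold: 15}
      - {nutrient: saturated_fat_g, basis: per_100g, comparator: "<=", threshold: 5}
      - {nutrient: trans_fat_g, basis: per_100g, comparator: "<=", threshold: 0.6}
      - {nutrient: sodium_mg, basis: per_100g, comparator: "<=", threshold: 400}
notes: >
  A food is approved only when it sits at or below all four limits;
  exceeding any one marks it "high in" that component and not permitted.
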