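# UK FSA/Ofcom nutrient profiling model (2004/2005, as used by Ofcom for
# broadcast advertising regulation). Points mode: A-points for energy,
# saturated fat, total sugars and sodium per 100 g; C-points for
# fruit/veg/nuts, fibre (NSP or AOAC assay) and protein. Score = A - C.
# "Less healthy" (not permitted) at a score of 4 or more for foods, 1 or
# more for drinks. Table transcribed from the official FSA/Department of
# Health technical guidance; bounds are strict lower bounds (a value must
# exceed the bound to earn the points).
model_id: uk
name: UK FSA/Ofcom nutrient profiling model
mode: points
points_table:
  a_components:
    energy_kJ:
      - [335, 1]
      - [670, 2]
      - [1005, 3]
      - [1340, 4]
      - [1675, 5]
      - [2010, 6]
      - [2345, 7]
      - [2680, 8]
      - [3015, 9]
      - [3350, 10]
    saturated_fat_g:
      - [1, 1]
      - [2, 2]
      - [3, 3]
      - [4, 4]
      - [5, 5]
      - [6, 6]
      - [7, 7]
      - [8, 8]
      - [9, 9]
      - [10, 10]
    total_sugar_g:
      - [4.5, 1]
      - [9, 2]
      - [13.5, 3]
      - [18, 4]
      - [22.5, 5]
      - [27, 6]
      - [31, 7]
      - [36, 8]
      - [40, 9]
      - [45, 10]
    sodium_mg:
      - [90, 1]
      - [180, 2]
      - [270, 3]
      - [360, 4]
      - [450, 5]
      - [540, 6]
      - [630, 7]
      - [720, 8]
      - [810, 9]
      - [900, 10]
  c_components:
    fruit_veg_nut_pct:
      - [40, 1]
      - [60, 2]
      - [80, 5]
    fibre_g_nsp:
      - [0.7, 1]
      - [1.4, 2]
      - [2.1, 3]
      - [2.8, 4]
      - [3.5, 5]
    fibre_g_aoac:
      - [0.9, 1]
      - [1.9, 2]
      - [2.8, 3]
      - [3.7, 4]
      - [4.7, 5]
    protein_g:
      - [1.6, 1]
      - [3.2, 2]
      - [4.8, 3]
      - [6.4, 4]
      - [8, 5]
  protein_cap_a_points: 11
  protein_exempt_fvn_points: 5
  fail_threshold_food: 4
  fail_threshold_drink: 1
notes: >
  Two categories (food and drink) via the pass thresholds. Protein may
  not be credited when A-points reach 11 unless fruit/veg/nuts scores the
  maximum 5 points.
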