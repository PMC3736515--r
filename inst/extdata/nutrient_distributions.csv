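category,nutrient,meanlog,sdlog,max
bread_cereals_potatoes,energy_kJ,7.35,0.25,3700
bread_cereals_potatoes,total_fat_g,1.6,0.7,30
bread_cereals_potatoes,saturated_fat_g,0.4,0.8,15
bread_cereals_potatoes,trans_fat_g,-3,1,2
bread_cereals_potatoes,cholesterol_mg,1.6,1,200
bread_cereals_potatoes,total_sugar_g,2.9,0.7,60
bread_cereals_potatoes,added_sugar_g,2.5,0.7,50
bread_cereals_potatoes,sodium_mg,6,0.6,1800
bread_cereals_potatoes,protein_g,2.1,0.4,25
bread_cereals_potatoes,fibre_g,1.4,0.6,15
bread_cereals_potatoes,fruit_veg_nut_pct,0.7,1.5,100
bread_cereals_potatoes,serving_size_g,3.7,0.3,150
composite,energy_kJ,6.68,0.3,2000
composite,total_fat_g,2.08,0.5,25
composite,saturated_fat_g,1.1,0.6,12
composite,trans_fat_g,-2.3,1,2
composite,cholesterol_mg,3.4,0.8,150
composite,total_sugar_g,1.4,0.7,20
composite,added_sugar_g,0.4,1,15
composite,sodium_mg,6.04,0.5,1500
composite,protein_g,2.2,0.4,25
composite,fibre_g,0.7,0.6,8
composite,fruit_veg_nut_pct,2.7,0.8,100
composite,serving_size_g,5.7,0.3,700
fatty_sugary_snack,energy_kJ,7.65,0.2,3700
fatty_sugary_snack,total_fat_g,3.09,0.5,45
fatty_sugary_snack,saturated_fat_g,2.2,0.6,30
fatty_sugary_snack,trans_fat_g,-1.6,1,3
fatty_sugary_snack,cholesterol_mg,2.3,1,100
fatty_sugary_snack,total_sugar_g,3.69,0.5,75
fatty_sugary_snack,added_sugar_g,3.56,0.5,70
fatty_sugary_snack,sodium_mg,5.7,1,2000
fatty_sugary_snack,protein_g,1.8,0.5,20
fatty_sugary_snack,fibre_g,0.4,0.7,8
fatty_sugary_snack,fruit_veg_nut_pct,0,1.5,100
fatty_sugary_snack,serving_size_g,3.55,0.3,120
fatty_sugary_not_snack,energy_kJ,7.38,0.4,3700
fatty_sugary_not_snack,total_fat_g,3.2,0.8,100
fatty_sugary_not_snack,saturated_fat_g,2.08,0.8,60
fatty_sugary_not_snack,trans_fat_g,-1.2,1,4
fatty_sugary_not_snack,cholesterol_mg,3,1,250
fatty_sugary_not_snack,total_sugar_g,2.7,0.9,65
fatty_sugary_not_snack,added_sugar_g,2.3,1,60
fatty_sugary_not_snack,sodium_mg,6.2,0.8,2500
fatty_sugary_not_snack,protein_g,1.1,0.7,15
fatty_sugary_not_snack,fibre_g,0,0.8,6
fatty_sugary_not_snack,fruit_veg_nut_pct,1.6,1.2,100
fatty_sugary_not_snack,serving_size_g,3.4,0.4,100
fatty_sugary_drink,energy_kJ,5.19,0.5,800
fatty_sugary_drink,total_fat_g,-2.3,0.8,3
fatty_sugary_drink,saturated_fat_g,-3,0.8,2
fatty_sugary_drink,trans_fat_g,-4.6,0.5,0.5
fatty_sugary_drink,cholesterol_mg,-0.7,0.8,10
fatty_sugary_drink,total_sugar_g,2.2,0.6,25
fatty_sugary_drink,added_sugar_g,2.08,0.6,22
fatty_sugary_drink,sodium_mg,2.7,0.8,200
fatty_sugary_drink,protein_g,-1.6,0.8,4
fatty_sugary_drink,fibre_g,-2.3,0.8,2
fatty_sugary_drink,fruit_veg_nut_pct,2.3,1.5,100
fatty_sugary_drink,serving_size_g,5.8,0.2,600
fruit_veg,energy_kJ,5.52,0.5,1500
fruit_veg,total_fat_g,-0.7,0.9,12
fruit_veg,saturated_fat_g,-2.3,0.9,3
fruit_veg,trans_fat_g,-4.6,0.5,0.3
fruit_veg,cholesterol_mg,-1.6,0.5,5
fruit_veg,total_sugar_g,1.95,0.6,25
fruit_veg,added_sugar_g,-1.2,1,8
fruit_veg,sodium_mg,3,1,400
fruit_veg,protein_g,0.7,0.5,8
fruit_veg,fibre_g,1.1,0.5,10
fruit_veg,fruit_veg_nut_pct,4.55,0.05,100
fruit_veg,serving_size_g,4.38,0.3,300
meat_fish_alternatives,energy_kJ,6.86,0.3,2200
meat_fish_alternatives,total_fat_g,2.4,0.5,35
meat_fish_alternatives,saturated_fat_g,1.25,0.6,15
meat_fish_alternatives,trans_fat_g,-2.3,1,2
meat_fish_alternatives,cholesterol_mg,4.09,0.5,300
meat_fish_alternatives,total_sugar_g,0.4,0.8,10
meat_fish_alternatives,added_sugar_g,-0.7,1,6
meat_fish_alternatives,sodium_mg,6.48,0.5,2200
meat_fish_alternatives,protein_g,2.7,0.3,35
meat_fish_alternatives,fibre_g,0,0.8,6
meat_fish_alternatives,fruit_veg_nut_pct,0.7,1.2,60
meat_fish_alternatives,serving_size_g,4.6,0.3,300
milk_dairy,energy_kJ,6.04,0.5,1800
milk_dairy,total_fat_g,1.39,0.7,35
milk_dairy,saturated_fat_g,0.92,0.7,22
milk_dairy,trans_fat_g,-2.3,0.8,2
milk_dairy,cholesterol_mg,2.48,0.6,120
milk_dairy,total_sugar_g,2.2,0.5,30
milk_dairy,added_sugar_g,1.39,0.9,20
milk_dairy,sodium_mg,4.5,0.7,900
milk_dairy,protein_g,1.39,0.4,12
milk_dairy,fibre_g,-1.6,0.8,3
milk_dairy,fruit_veg_nut_pct,1.1,1.2,60
milk_dairy,serving_size_g,4.83,0.4,500
miscellaneous,energy_kJ,6.8,0.6,3000
miscellaneous,total_fat_g,2.08,0.8,40
miscellaneous,saturated_fat_g,0.92,0.8,18
miscellaneous,trans_fat_g,-2.3,1,2
miscellaneous,cholesterol_mg,2.7,1,150
miscellaneous,total_sugar_g,2.3,0.9,55
miscellaneous,added_sugar_g,1.6,1,40
miscellaneous,sodium_mg,5.86,0.8,2000
miscellaneous,protein_g,1.6,0.6,20
miscellaneous,fibre_g,0.4,0.7,8
miscellaneous,fruit_veg_nut_pct,1.6,1.3,100
miscellaneous,serving_size_g,4.6,0.4,400
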