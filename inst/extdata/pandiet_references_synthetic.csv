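nutrient_id,sex,age_band,reference,direction
protein_g,all,all,60,at_least
fibre_g,all,all,30,at_least
vitamin_a_ug,all,all,750,at_least
thiamin_mg,all,all,1.2,at_least
riboflavin_mg,all,all,1.6,at_least
niacin_mg,all,all,14,at_least
vitamin_b6_mg,all,all,1.7,at_least
folate_ug,all,all,330,at_least
vitamin_b12_ug,all,all,4,at_least
vitamin_c_mg,all,all,110,at_least
vitamin_d_ug,all,all,15,at_least
vitamin_e_mg,all,all,10,at_least
calcium_mg,all,all,950,at_least
magnesium_mg,all,all,380,at_least
potassium_mg,all,all,3500,at_least
iron_mg,all,all,11,at_least
zinc_mg,all,all,11,at_least
copper_mg,all,all,1.5,at_least
selenium_ug,all,all,70,at_least
iodine_ug,all,all,150,at_least
phosphorus_mg,all,all,700,at_least
manganese_mg,all,all,2.5,at_least
sugars_g,all,all,100,at_most
saturated_fat_g,all,all,22,at_most
sodium_g,all,all,2.3,at_most
cholesterol_g,all,all,0.3,at_most
total_fat_g,all,all,97,at_most
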