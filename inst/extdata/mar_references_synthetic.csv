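nutrient_id,sex,age_band,rda
protein_g,all,all,60
fibre_g,all,all,30
vitamin_a_ug,all,all,750
thiamin_mg,all,all,1.2
riboflavin_mg,all,all,1.6
niacin_mg,all,all,14
vitamin_b6_mg,all,all,1.7
folate_ug,all,all,330
vitamin_b12_ug,all,all,4
vitamin_c_mg,all,all,110
vitamin_d_ug,all,all,15
vitamin_e_mg,all,all,10
calcium_mg,all,all,950
magnesium_mg,all,all,380
potassium_mg,all,all,3500
iron_mg,all,all,11
zinc_mg,all,all,11
copper_mg,all,all,1.5
selenium_ug,all,all,70
iodine_ug,all,all,150
phosphorus_mg,all,all,700
manganese_mg,all,all,2.5
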