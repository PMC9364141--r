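commodity,group,water_km3,n_kt,p_kt,ghg_mt,cropland_kha
live_cattle,animal_products,NA,NA,NA,142,NA
dairy_cattle,animal_products,NA,NA,NA,46,NA
live_poultry,animal_products,NA,NA,NA,25,NA
other_live_animals,animal_products,NA,NA,NA,30,NA
grain_farms,crops,46,8320,1244,69,NA
fruit_nut_farms,crops,7,103,13,1,NA
vegetable_melon_farms,crops,9,229,62,6,NA
oilseed_farms,crops,18,205,180,13,NA
other_crops,crops,14,1210,137,3,NA
soya_oil_processing,food_processing,0,0,0,10,NA
sugar_processing,food_processing,0,0,0,2,NA
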