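category,weight_g,energy_mj,sodium_mg
all_other_foods,94.1,1.3,1114.6
all_other_foods_good,57.3,0.5,128.4
beef,27.2,0.2,23.3
breads_rolls,113.3,1.2,494.0
cereals,84.0,1.3,148.9
dairy_not_milk,6.1,0.1,38.6
diet_drinks,70.3,0.0,8.2
fruit_fresh,36.2,0.1,0.7
fruit_other,3.9,0.0,0.3
lamb,12.5,0.1,6.9
margarine,13.9,0.3,72.6
milk,54.0,0.6,92.3
other_drinks,156.3,0.4,20.9
other_meats,48.5,0.4,328.0
pork,0.8,0.0,0.6
poultry,29.2,0.2,33.6
soft_drinks,357.0,0.6,56.2
sugar,80.0,1.1,4.2
tea_coffee,7.6,0.0,0.4
vegetables_fresh_frozen,50.7,0.1,7.9
vegetables_other,14.4,0.1,42.4
water,43.7,0.0,0.6
total,1360.7,8.5,2623.5
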