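arm,period,category,metric,basis,mean,lo,hi
discount_only,during,all_other_foods,weight,absolute,8.0,-0.4,17.2
discount_only,during,all_other_foods_good,weight,absolute,1.6,-2.7,6.3
discount_only,during,beef,weight,absolute,-0.3,-4.0,4.0
discount_only,during,breads_rolls,weight,absolute,6.3,-1.5,14.6
discount_only,during,cereals,weight,absolute,9.3,1.5,17.7
discount_only,during,dairy_not_milk,weight,absolute,0.6,-0.2,1.5
discount_only,during,diet_drinks,weight,absolute,4.3,-3.3,12.7
discount_only,during,fruit_fresh,weight,absolute,6.9,1.9,12.5
discount_only,during,fruit_other,weight,absolute,1.0,0.1,2.2
discount_only,during,lamb,weight,absolute,2.0,-1.0,5.9
discount_only,during,margarine,weight,absolute,0.5,-0.5,1.6
discount_only,during,milk,weight,absolute,1.9,-1.8,5.9
discount_only,during,other_drinks,weight,absolute,7.4,-6.9,23.1
discount_only,during,other_meats,weight,absolute,0.8,-4.2,6.3
discount_only,during,pork,weight,absolute,-0.0,-0.3,0.4
discount_only,during,poultry,weight,absolute,1.6,-2.2,5.9
discount_only,during,soft_drinks,weight,absolute,19.5,-10.9,52.6
discount_only,during,sugar,weight,absolute,0.9,-5.9,8.3
discount_only,during,tea_coffee,weight,absolute,0.4,-0.2,1.1
discount_only,during,vegetables_fresh_frozen,weight,absolute,4.5,0.5,8.9
discount_only,during,vegetables_other,weight,absolute,2.0,0.4,3.8
discount_only,during,water,weight,absolute,7.5,0.3,15.8
discount_only,during,total,weight,absolute,88.2,-2.8,185.4
discount_only,followup,all_other_foods,weight,absolute,17.4,3.6,33.2
discount_only,followup,all_other_foods_good,weight,absolute,3.9,-2.8,11.4
discount_only,followup,beef,weight,absolute,-0.5,-5.9,6.3
discount_only,followup,breads_rolls,weight,absolute,9.9,-2.2,23.3
discount_only,followup,cereals,weight,absolute,15.66,3.49,29.5
discount_only,followup,dairy_not_milk,weight,absolute,1.0,-0.3,2.6
discount_only,followup,diet_drinks,weight,absolute,-0.6,-11.1,11.9
discount_only,followup,fruit_fresh,weight,absolute,9.9,2.1,19.3
discount_only,followup,fruit_other,weight,absolute,0.8,-0.5,2.7
discount_only,followup,lamb,weight,absolute,2.2,-2.3,8.7
discount_only,followup,margarine,weight,absolute,1.4,-0.3,3.2
discount_only,followup,milk,weight,absolute,4.9,-1.0,11.4
discount_only,followup,other_drinks,weight,absolute,9.5,-12.3,34.6
discount_only,followup,other_meats,weight,absolute,2.7,-5.1,11.9
discount_only,followup,pork,weight,absolute,-0.1,-0.5,0.5
discount_only,followup,poultry,weight,absolute,4.5,-1.6,12.0
discount_only,followup,soft_drinks,weight,absolute,17.3,-27.9,68.8
discount_only,followup,sugar,weight,absolute,1.8,-8.5,13.5
discount_only,followup,tea_coffee,weight,absolute,0.6,-0.3,1.7
discount_only,followup,vegetables_fresh_frozen,weight,absolute,8.2,1.9,15.4
discount_only,followup,vegetables_other,weight,absolute,2.0,-0.4,4.8
discount_only,followup,water,weight,absolute,5.1,-4.9,17.8
discount_only,followup,total,weight,absolute,127.0,-14.0,282.8
discount_plus_education,during,all_other_foods,weight,absolute,4.9,-7.4,19.0
discount_plus_education,during,all_other_foods_good,weight,absolute,7.1,0.2,14.8
discount_plus_education,during,beef,weight,absolute,5.1,-1.6,13.4
discount_plus_education,during,breads_rolls,weight,absolute,12.3,-0.1,25.9
discount_plus_education,during,cereals,weight,absolute,13.0,2.2,25.1
discount_plus_education,during,dairy_not_milk,weight,absolute,1.9,0.5,3.6
discount_plus_education,during,diet_drinks,weight,absolute,5.0,-6.2,18.1
discount_plus_education,during,fruit_fresh,weight,absolute,8.2,1.1,16.6
discount_plus_education,during,fruit_other,weight,absolute,1.2,-0.2,3.0
discount_plus_education,during,lamb,weight,absolute,2.1,-2.5,8.8
discount_plus_education,during,margarine,weight,absolute,0.3,-1.1,1.9
discount_plus_education,during,milk,weight,absolute,3.2,-2.2,9.1
discount_plus_education,during,other_drinks,weight,absolute,24.1,0.1,51.8
discount_plus_education,during,other_meats,weight,absolute,1.5,-6.8,11.4
discount_plus_education,during,pork,weight,absolute,0.1,-0.3,0.8
discount_plus_education,during,poultry,weight,absolute,3.8,-1.9,10.7
discount_plus_education,during,soft_drinks,weight,absolute,48.5,0.3,103.1
discount_plus_education,during,sugar,weight,absolute,6.1,-5.1,18.9
discount_plus_education,during,tea_coffee,weight,absolute,1.0,0.1,2.1
discount_plus_education,during,vegetables_fresh_frozen,weight,absolute,13.4,7.1,20.4
discount_plus_education,during,vegetables_other,weight,absolute,1.3,-1.0,4.0
discount_plus_education,during,water,weight,absolute,12.7,1.5,26.6
discount_plus_education,during,total,weight,absolute,161.1,16.6,320.8
discount_plus_education,followup,all_other_foods,weight,absolute,15.8,0.7,33.3
discount_plus_education,followup,all_other_foods_good,weight,absolute,6.6,-1.1,15.2
discount_plus_education,followup,beef,weight,absolute,-0.2,-6.3,7.7
discount_plus_education,followup,breads_rolls,weight,absolute,9.9,-3.5,25.0
discount_plus_education,followup,cereals,weight,absolute,18.8,5.7,33.9
discount_plus_education,followup,dairy_not_milk,weight,absolute,1.9,0.4,3.8
discount_plus_education,followup,diet_drinks,weight,absolute,2.6,-9.5,16.9
discount_plus_education,followup,fruit_fresh,weight,absolute,4.5,-2.8,13.4
discount_plus_education,followup,fruit_other,weight,absolute,1.1,-0.4,3.2
discount_plus_education,followup,lamb,weight,absolute,2.1,-2.9,9.7
discount_plus_education,followup,margarine,weight,absolute,1.7,-0.0,3.7
discount_plus_education,followup,milk,weight,absolute,5.8,-0.5,13.0
discount_plus_education,followup,other_drinks,weight,absolute,11.3,-13.3,40.1
discount_plus_education,followup,other_meats,weight,absolute,-2.1,-10.4,8.1
discount_plus_education,followup,pork,weight,absolute,-0.1,-0.4,0.6
discount_plus_education,followup,poultry,weight,absolute,7.9,0.8,16.8
discount_plus_education,followup,soft_drinks,weight,absolute,26.8,-23.9,85.1
discount_plus_education,followup,sugar,weight,absolute,1.8,-9.8,15.3
discount_plus_education,followup,tea_coffee,weight,absolute,1.1,0.1,2.3
discount_plus_education,followup,vegetables_fresh_frozen,weight,absolute,14.6,7.2,22.9
discount_plus_education,followup,vegetables_other,weight,absolute,1.3,-1.2,4.3
discount_plus_education,followup,water,weight,absolute,2.3,-7.9,15.4
discount_plus_education,followup,total,weight,absolute,128.8,-28.0,303.9
discount_only,during,total,energy,absolute,0.57,0.01,1.18
discount_plus_education,during,total,energy,absolute,0.92,0.05,1.87
discount_only,followup,total,energy,absolute,1.18,0.27,2.18
discount_plus_education,followup,total,energy,absolute,1.18,0.19,2.29
discount_only,during,total,sodium,absolute,216.67,13.86,435.07
discount_plus_education,during,total,sodium,absolute,264.26,-19.80,579.30
discount_only,followup,total,sodium,absolute,362.46,46.05,716.38
discount_plus_education,followup,total,sodium,absolute,232.55,-87.0,592.4
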