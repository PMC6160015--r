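item,strategy,phase,amount_aud,hours
graphic_design_discount_promotion,discount,design,2068,NA
printing_distribution_discount_materials,discount,design,9641,NA
design_coordination_time,discount,design,7434,125
discount_reimbursement_to_stores,discount,implementation,221111,NA
trial_staff_discount_promotion,discount,implementation,17956,115
travel_accommodation_discount_promotion,discount,implementation,10627,NA
coordination_monitoring_evaluation_discount,discount,implementation,50658,842
store_manager_discount_promotion,discount,implementation,38779,960
graphic_design_education_materials,education,design,20579,NA
printing_distribution_education_materials,education,design,12323,NA
education_coordination_time,education,design,34084,515
recruitment_training_community_coordinators,education,implementation,37061,330
travel_accommodation_recruiter_trainers,education,implementation,22764,NA
materials_prizes_education_activities,education,implementation,15532,NA
community_coordinators_phn_time,education,implementation,13363,341
community_member_participation_time,education,implementation,1048,171
coordination_monitoring_evaluation_education,education,implementation,78803,1225
store_manager_education_support,education,implementation,9695,240
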