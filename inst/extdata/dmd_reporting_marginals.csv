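# Published aggregated reporting-quality percentages (% of studies answering
# yes) for the drug-intervention studies behind the DMD validation case:
# mdx mouse (N = 32) and GRMD dog (N = 3). Empty cells mark parameters not
# applicable to any study in the group.
parameter,mdx mouse,GRMD dog
type_of_facility,6.3,0.0
type_of_cage_or_housing,12.5,0.0
bedding_material,0.0,0.0
number_of_cage_companions,12.5,0.0
breeding_programme,53.1,100.0
light_dark_cycle,25.0,0.0
temperature_and_humidity,3.1,0.0
water_quality_fish,,
type_of_food,6.3,0.0
access_to_food_and_water,34.4,0.0
environmental_enrichment,0.0,0.0
any_blinding,43.8,33.3
any_randomisation,34.4,0.0
sample_size,84.4,100.0
sample_size_calculation,6.3,33.3
acclimatisation,18.8,0.0
sex_disclosed,46.9,33.3
background_control,,
background_model,,
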