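# Published aggregated risk-of-bias percentages (% of studies at low /
# unclear risk; the remainder is high risk) for the DMD intervention
# studies: mdx mouse (N = 32) and GRMD dog (N = 3).
parameter,mdx mouse_low,mdx mouse_unclear,GRMD dog_low,GRMD dog_unclear
allocation_concealment,0.0,100.0,0.0,100.0
blinded_outcome_assessment,3.1,96.8,0.0,100.0
blinded_operations,0.0,100.0,0.0,100.0
random_cage_allocation,0.0,100.0,0.0,100.0
random_outcome_assessment,0.0,100.0,0.0,100.0
sequence_generation,0.0,96.8,0.0,100.0
baseline_characteristics,3.1,96.8,0.0,100.0
incomplete_outcome_data,18.8,67.7,0.0,100.0
selective_outcome_reporting,96.9,3.2,100.0,0.0
other,71.9,6.5,33.3,0.0
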