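# Reference whole-body compartment table for a 60-kg, 1.7-m adult male.
# Flows and volumes follow the Bae-style whole-body circulation model, with
# stomach, spleen, pancreas and myocardium split out as separate compartments
# using Leggett & Williams resting regional blood-flow fractions, normalized
# so that left-heart output is exactly 6500 ml/min. Values are
# literature-derived approximations (see package vignette); edit freely.
# Columns: name, blood_flow (ml/min), v_iv (ml, intravascular),
#          v_ec (ml, extracellular), n_sub (tanks in series),
#          k_tc (1/min, transcapillary exchange coefficient)
name	blood_flow	v_iv	v_ec	n_sub	k_tc
peripheral_vein	1300	100	0	15	0
right_heart	6500	180	0	15	0
lungs	6500	500	500	15	1.5
left_heart	6500	180	0	15	0
ascending_aorta	6500	70	0	15	0
abdominal_aorta	4940	120	0	15	0
upper_body	1300	800	4000	15	0.5
myocardium	260	50	100	15	1.0
kidneys	1235	150	250	15	2.0
liver	1625	450	1000	15	2.0
stomach	65	30	100	15	1.0
spleen	195	150	150	15	2.0
pancreas	65	25	80	15	1.0
intestine	880	300	900	15	1.5
lower_body	2080	1000	5500	15	0.5
systemic_veins	5200	495	0	15	0
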