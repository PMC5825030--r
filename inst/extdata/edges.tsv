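# Directed blood-flow topology of the reference network (flows in ml/min for
# the unscaled 60-kg reference; every compartment's inflow equals its outflow).
from	to	flow
left_heart	ascending_aorta	6500
ascending_aorta	myocardium	260
ascending_aorta	upper_body	1300
ascending_aorta	abdominal_aorta	4940
abdominal_aorta	kidneys	1235
abdominal_aorta	liver	420
abdominal_aorta	stomach	65
abdominal_aorta	spleen	195
abdominal_aorta	pancreas	65
abdominal_aorta	intestine	880
abdominal_aorta	lower_body	2080
stomach	liver	65
spleen	liver	195
pancreas	liver	65
intestine	liver	880
liver	systemic_veins	1625
kidneys	systemic_veins	1235
lower_body	systemic_veins	2080
myocardium	systemic_veins	260
upper_body	peripheral_vein	1300
peripheral_vein	right_heart	1300
systemic_veins	right_heart	5200
right_heart	lungs	6500
lungs	left_heart	6500
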