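feature,affected,assessed
poikiloderma,32,32
hypotrichosis,27,30
hypohidrosis,24,27
muscle_finding,9,11
tendon_contractures,13,18
muscle_impairment,16,23
other_tegument_abnormalities,19,29
muscle_weakness,10,18
endocrine_impairment,3,3
pancreas_impairment,14,32
liver_impairment,16,32
growth_retardation,7,14
lung_impairment,9,27
renal_insufficiency,2,2
spinal_deformity,3,12
abnormal_blood_count,4,12
teeth_abnormalities,1,3
severe_muscle_impairment,2,32
ophthalmologic_abnormalities,2,11
severe_hypotrophy,6,22
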