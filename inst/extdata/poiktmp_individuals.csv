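id,sex,age,protein_variant,inheritance,poikiloderma,hypotrichosis,hypohidrosis,muscle_finding,tendon_contractures,muscle_impairment,other_tegument_abnormalities,muscle_weakness,endocrine_impairment,pancreas_impairment,liver_impairment,growth_retardation,lung_impairment,renal_insufficiency,spinal_deformity,abnormal_blood_count,teeth_abnormalities,severe_muscle_impairment,ophthalmologic_abnormalities,severe_hypotrophy
I1,M,11,p.(Tyr434Ser),inherited,1,0,1,NA,0,0,1,0,0,1,1,0,NA,0,0,0,0,0,0,NA
I2,F,47,p.(Tyr434Ser),de novo,1,1,1,NA,1,1,1,1,0,1,0,0,NA,0,1,0,0,0,0,NA
I3,F,35,p.(Arg627Gly),assumed inherited,1,1,1,NA,1,1,1,1,0,1,0,0,0,NA,1,0,0,0,0,NA
I4,M,48,p.(Arg627Gly),NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
F1,M,18,p.(Arg627Gly),de novo,1,1,1,1,1,1,1,1,0,1,0,1,1,0,1,1,0,1,0,NA
F2,M,12,p.(Arg627Gly),paternal,1,1,1,NA,1,1,0,1,NA,1,1,0,0,0,0,0,NA,0,0,NA
F4,F,15,p.(Ser628Asn),assumed de novo,1,1,1,1,1,1,1,1,NA,0,0,1,1,NA,0,1,NA,1,0,NA
F5,F,12,p.(Ser628Asn),de novo,1,1,1,1,1,1,1,1,1,0,0,1,0,1,0,0,1,1,0,NA
F8,M,17,p.(Thr625Asn),de novo,1,1,0,NA,1,1,1,1,NA,0,0,0,1,0,0,0,NA,0,0,NA
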