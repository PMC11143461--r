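# Serious-illness diagnosis categories as ICD-10 code prefixes.
# Transcribed at prefix (category-family) level from the commonly used
# life-limiting-illness code families; fully overridable: supply your own
# file to flag_serious_illness()/read_diagnosis_catalog().
stroke_tia: [I60, I61, I62, I63, G45]
liver_disease: [K70, K71, K72, K73, K74, K76]
hip_fracture: [S72]
cancer: [C]
heart_disease: [I42, I50]
lung_disease: [J43, J44, J47, J84, J96]
neurodegenerative_disease: [G10, G12, G13, G20, G23, G35]
diabetes_with_pvd: [E10.5, E11.5, E13.5]
coronary_artery_disease: [I25]
chronic_kidney_disease: [N18]
hiv_aids: [B20, B21, B22, B24]
kidney_failure: [N17, N19]
dementia: [F01, F02, F03, F05, G30]
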