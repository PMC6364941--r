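name,mean_conc,field_400,field_900,in_classification
alanine,0.35,1,1,1
arginine,0.08,1,1,1
asparagine,0.04,1,1,1
aspartate,0.02,1,1,1
cysteine,0.03,1,1,1
glutamine,0.50,1,1,1
glutamate,0.06,1,1,1
glycine,0.25,1,1,1
histidine,0.08,1,1,1
isoleucine,0.06,1,1,1
leucine,0.12,1,1,1
lysine,0.18,1,1,1
methionine,0.025,1,1,1
phenylalanine,0.06,1,1,1
proline,0.17,1,1,1
serine,0.11,1,1,1
threonine,0.13,1,1,1
tryptophan,0.05,1,1,1
tyrosine,0.06,1,1,1
valine,0.22,1,1,1
alpha-D-glucopyranose,1.80,1,1,1
beta-D-glucopyranose,2.90,1,1,1
myo-inositol,0.03,1,1,1
acetate,0.04,1,1,1
acetoacetate,0.03,1,1,1
alpha-ketoglutarate,0.02,1,1,1
beta-hydroxybutyrate,0.06,1,1,1
citrate,0.11,1,1,1
lactate,1.50,1,1,1
pyruvate,0.06,1,1,1
succinate,0.02,1,1,1
creatine,0.035,1,1,1
creatinine,0.07,1,1,1
betaine,0.04,0,1,0
choline,0.01,0,1,0
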