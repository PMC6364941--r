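metabolite,multiplet_id,center_ppm,pattern,j_hz,protons,rel_intensities,raster_file,shift_tolerance_ppm
alanine,ala_d,1.509,doublet,7.2,3,,,0.005
alanine,ala_q,3.810,quartet,7.2,1,,,0.005
arginine,arg_t,3.240,triplet,6.9,2,,,0.005
arginine,arg_t2,1.900,triplet,7.0,2,,,0.005
asparagine,asn_dd1,2.860,double_doublet,16.9;7.6,1,,,0.005
asparagine,asn_dd2,2.950,double_doublet,16.9;4.3,1,,,0.005
aspartate,asp_dd1,2.702,double_doublet,17.4;9.0,1,,,0.005
aspartate,asp_dd2,2.810,double_doublet,17.4;3.9,1,,,0.005
cysteine,cys_dd,3.040,double_doublet,14.4;7.0,2,,,0.005
glutamine,gln_t1,2.450,triplet,7.6,2,,,0.005
glutamine,gln_t2,2.140,triplet,7.8,2,,,0.005
glutamate,glu_t1,2.350,triplet,7.5,2,,,0.005
glutamate,glu_t2,2.080,triplet,7.6,2,,,0.005
glycine,gly_s,3.560,singlet,,2,,,0.005
histidine,his_s1,7.080,singlet,,1,,,0.005
histidine,his_s2,7.790,singlet,,1,,,0.005
isoleucine,ile_t,0.940,triplet,7.4,3,,,0.005
isoleucine,ile_d,1.010,doublet,7.0,3,,,0.005
leucine,leu_d,0.961,doublet,6.2,6,,,0.005
lysine,lys_t,3.027,triplet,7.6,2,,,0.005
lysine,lys_t2,1.720,triplet,7.3,2,,,0.005
methionine,met_s,2.135,singlet,,3,,,0.005
methionine,met_t,2.640,triplet,7.6,2,,,0.005
phenylalanine,phe_d,7.330,doublet,7.6,2,,,0.005
phenylalanine,phe_t,7.420,triplet,7.4,3,,,0.005
proline,pro_dd,4.130,double_doublet,8.6;6.4,1,,,0.005
proline,pro_t,3.340,triplet,6.8,2,,,0.005
serine,ser_dd1,3.840,double_doublet,12.3;5.0,1,,,0.005
serine,ser_dd2,3.960,double_doublet,12.3;3.9,1,,,0.005
threonine,thr_d,1.318,doublet,6.6,3,,,0.005
tryptophan,trp_d1,7.540,doublet,7.9,1,,,0.005
tryptophan,trp_d2,7.730,doublet,8.0,1,,,0.005
tryptophan,trp_s,7.280,singlet,,1,,,0.005
tyrosine,tyr_d1,6.900,doublet,8.5,2,,,0.005
tyrosine,tyr_d2,7.190,doublet,8.5,2,,,0.005
tyrosine,tyr_dd,3.100,double_doublet,14.6;5.1,1,,,0.005
valine,val_d1,0.990,doublet,7.0,3,,,0.005
valine,val_d2,1.040,doublet,7.0,3,,,0.005
alpha-D-glucopyranose,glca_d,5.230,doublet,3.8,1,,,0.005
alpha-D-glucopyranose,glca_dd,3.530,double_doublet,9.8;3.8,1,,,0.005
beta-D-glucopyranose,glcb_d,4.650,doublet,8.0,1,,,0.005
beta-D-glucopyranose,glcb_dd,3.250,double_doublet,9.4;8.0,1,,,0.005
myo-inositol,ino_t1,3.280,triplet,9.4,1,,,0.005
myo-inositol,ino_t2,4.060,triplet,2.9,1,,,0.005
acetate,ace_s,1.920,singlet,,3,,,0.005
acetoacetate,aca_s1,2.280,singlet,,3,,,0.005
acetoacetate,aca_s2,3.440,singlet,,2,,,0.005
alpha-ketoglutarate,akg_t1,3.010,triplet,6.9,2,,,0.005
alpha-ketoglutarate,akg_t2,2.440,triplet,6.9,2,,,0.005
beta-hydroxybutyrate,bhb_d,1.200,doublet,6.3,3,,,0.005
beta-hydroxybutyrate,bhb_dd,2.310,double_doublet,14.0;7.0,1,,,0.005
citrate,cit_d1,2.717,doublet,15.9,2,1.2;0.8,,0.005
citrate,cit_d2,2.566,doublet,15.9,2,0.8;1.2,,0.005
lactate,lac_d,1.326,doublet,6.9,3,,,0.005
lactate,lac_q,4.110,quartet,6.9,1,,,0.005
pyruvate,pyr_s,2.370,singlet,,3,,,0.005
succinate,suc_s,2.394,singlet,,4,,,0.005
creatine,cre_s,3.035,singlet,,3,,,0.005
creatine,cre_s2,3.930,singlet,,2,,,0.005
creatinine,crn_s,3.045,singlet,,3,,,0.005
creatinine,crn_s2,4.055,singlet,,2,,,0.005
betaine,bet_s,3.270,singlet,,9,,,0.005
betaine,bet_s2,3.900,singlet,,2,,,0.005
choline,cho_s,3.210,singlet,,9,,,0.005
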