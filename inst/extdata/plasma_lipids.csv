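lipid_id,label,center_ppm,fwhm_hz,mean_level
chol_ch3,cholesterol C18 methyl,0.68,25,0.4
lip_ch3,CH3-(CH2)n fatty acid chain methyl,0.88,25,2.5
lip_ch2n,-(CH2)n- methylene envelope,1.29,30,6.0
lip_ch2ch2co,-CH2-CH2-C=O,1.57,30,1.2
lip_allylic_nag,-CH2-CH=CH- + N-acetyl glycoprotein CH3,2.03,35,1.5
lip_ch2co,-CH2-C=O,2.24,35,1.0
lip_diallylic,=CH-CH2-CH=,2.77,35,0.6
lysyl,lysyl,3.00,40,0.8
lip_vinyl,-CH=CH- olefinic,5.32,40,1.2
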