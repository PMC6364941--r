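lipid_id,resonance_label,ppm_lo,ppm_hi
chol_ch3,cholesterol C18 methyl,0.60,0.74
lip_ch3,CH3-(CH2)n fatty acid chain methyl,0.80,0.95
lip_ch2n_a,-(CH2)n- methylene envelope (upfield),1.20,1.31
lip_ch2n_b,-(CH2)n- methylene envelope (downfield),1.31,1.42
lip_ch2ch2co,-CH2-CH2-C=O,1.50,1.65
lip_allylic_nag,-CH2-CH=CH- + NAG CH3,1.95,2.12
lip_ch2co,-CH2-C=O,2.18,2.30
lip_diallylic,=CH-CH2-CH=,2.70,2.85
lysyl,lysyl,2.92,3.08
lip_vinyl,-CH=CH- olefinic,5.24,5.44
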