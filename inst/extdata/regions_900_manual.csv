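"region_id","ppm_lo","ppm_hi","annotation","category"
"R001",0.6467,0.6633,"chol_ch3","lipid"
"R002",0.6633,0.68,"chol_ch3","lipid"
"R003",0.68,0.6967,"chol_ch3","lipid"
"R004",0.6967,0.7133,"chol_ch3","lipid"
"R005",0.8467,0.8633,"lip_ch3","lipid"
"R006",0.8633,0.88,"lip_ch3","lipid"
"R007",0.88,0.8967,"lip_ch3","lipid"
"R008",0.8967,0.9133,"lip_ch3","lipid"
"R009",0.9238,0.9481,"isoleucine+leucine","metabolite"
"R010",0.9481,0.9724,"isoleucine+leucine","metabolite"
"R011",0.9781,1,"isoleucine+valine","metabolite"
"R012",1,1.0219,"isoleucine+valine","metabolite"
"R013",1.0281,1.0519,"valine","metabolite"
"R014",1.1885,1.2115,"beta-hydroxybutyrate","metabolite"
"R015",1.25,1.272,"lactate+lip_ch2n+threonine","mixed"
"R016",1.272,1.2939,"lactate+lip_ch2n+threonine","mixed"
"R017",1.2939,1.3159,"lactate+lip_ch2n+threonine","mixed"
"R018",1.3159,1.3378,"lactate+lip_ch2n+threonine","mixed"
"R019",1.497,1.521,"alanine","metabolite"
"R020",1.53,1.55,"lip_ch2ch2co","lipid"
"R021",1.55,1.57,"lip_ch2ch2co","lipid"
"R022",1.57,1.59,"lip_ch2ch2co","lipid"
"R023",1.59,1.61,"lip_ch2ch2co","lipid"
"R024",1.7039,1.72,"lysine","metabolite"
"R025",1.72,1.7361,"lysine","metabolite"
"R026",1.8842,1.9061,"acetate+arginine","metabolite"
"R027",1.9061,1.928,"acetate+arginine","metabolite"
"R028",1.9833,2.0116,"glutamate+lip_allylic_nag","mixed"
"R029",2.0116,2.0399,"glutamate+lip_allylic_nag","mixed"
"R030",2.0399,2.0682,"glutamate+lip_allylic_nag","mixed"
"R031",2.0682,2.0964,"glutamate+lip_allylic_nag","mixed"
"R032",2.1233,2.14,"glutamine+methionine","metabolite"
"R033",2.14,2.1567,"glutamine+methionine","metabolite"
"R034",2.1933,2.217,"acetoacetate+lip_ch2co","mixed"
"R035",2.217,2.2407,"acetoacetate+lip_ch2co","mixed"
"R036",2.2407,2.2643,"acetoacetate+lip_ch2co","mixed"
"R037",2.2643,2.288,"acetoacetate+lip_ch2co","mixed"
"R038",2.2903,2.31,"beta-hydroxybutyrate","metabolite"
"R039",2.31,2.3297,"beta-hydroxybutyrate","metabolite"
"R040",2.3337,2.3558,"glutamate+pyruvate","metabolite"
"R041",2.3558,2.378,"glutamate+pyruvate","metabolite"
"R042",2.386,2.402,"succinate","metabolite"
"R043",2.4243,2.4454,"alpha-ketoglutarate+glutamine","metabolite"
"R044",2.4454,2.4664,"alpha-ketoglutarate+glutamine","metabolite"
"R045",2.5492,2.566,"citrate","metabolite"
"R046",2.566,2.5828,"citrate","metabolite"
"R047",2.6236,2.64,"methionine","metabolite"
"R048",2.64,2.6564,"methionine","metabolite"
"R049",2.6793,2.6981,"aspartate+citrate+lip_diallylic","mixed"
"R050",2.6981,2.717,"aspartate+citrate+lip_diallylic","mixed"
"R051",2.717,2.7358,"aspartate+citrate+lip_diallylic","mixed"
"R052",2.7358,2.7546,"aspartate+citrate+lip_diallylic","mixed"
"R053",2.7546,2.7734,"aspartate+citrate+lip_diallylic","mixed"
"R054",2.7734,2.7922,"aspartate+citrate+lip_diallylic","mixed"
"R055",2.7922,2.811,"aspartate+citrate+lip_diallylic","mixed"
"R056",2.811,2.8298,"aspartate+citrate+lip_diallylic","mixed"
"R057",2.8384,2.86,"asparagine","metabolite"
"R058",2.86,2.8816,"asparagine","metabolite"
"R059",2.9302,2.9464,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R060",2.9464,2.9626,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R061",2.9626,2.9788,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R062",2.9788,2.9951,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R063",2.9951,3.0113,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R064",3.0113,3.0275,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R065",3.0275,3.0437,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R066",3.0437,3.0599,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R067",3.0811,3.1,"tyrosine","metabolite"
"R068",3.1,3.1189,"tyrosine","metabolite"
"R069",3.202,3.218,"choline","metabolite"
"R070",3.2243,3.2429,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R071",3.2429,3.2614,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R072",3.2614,3.2799,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R073",3.2799,3.2984,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R074",3.3244,3.34,"proline","metabolite"
"R075",3.34,3.3556,"proline","metabolite"
"R076",3.432,3.448,"acetoacetate","metabolite"
"R077",3.5144,3.53,"alpha-D-glucopyranose","metabolite"
"R078",3.53,3.5456,"alpha-D-glucopyranose","metabolite"
"R079",3.552,3.568,"glycine","metabolite"
"R080",3.79,3.8069,"alanine+serine","metabolite"
"R081",3.8069,3.8238,"alanine+serine","metabolite"
"R082",3.8238,3.8407,"alanine+serine","metabolite"
"R083",3.8407,3.8576,"alanine+serine","metabolite"
"R084",3.892,3.908,"betaine","metabolite"
"R085",3.922,3.938,"creatine","metabolite"
"R086",3.943,3.96,"serine","metabolite"
"R087",3.96,3.977,"serine","metabolite"
"R088",4.047,4.0712,"creatinine+myo-inositol","metabolite"
"R089",4.0905,4.1184,"lactate+proline","metabolite"
"R090",4.1184,4.1463,"lactate+proline","metabolite"
"R091",5.2199,5.2401,"alpha-D-glucopyranose","metabolite"
"R092",5.2667,5.2933,"lip_vinyl","lipid"
"R093",5.2933,5.32,"lip_vinyl","lipid"
"R094",5.32,5.3467,"lip_vinyl","lipid"
"R095",5.3467,5.3733,"lip_vinyl","lipid"
"R096",6.8873,6.9127,"tyrosine","metabolite"
"R097",7.072,7.088,"histidine","metabolite"
"R098",7.1773,7.2027,"tyrosine","metabolite"
"R099",7.272,7.288,"tryptophan","metabolite"
"R100",7.3178,7.3422,"phenylalanine","metabolite"
"R101",7.4038,7.42,"phenylalanine","metabolite"
"R102",7.42,7.4362,"phenylalanine","metabolite"
"R103",7.5276,7.5524,"tryptophan","metabolite"
"R104",7.7176,7.7424,"tryptophan","metabolite"
"R105",7.782,7.798,"histidine","metabolite"
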