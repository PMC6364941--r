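"region_id","ppm_lo","ppm_hi","annotation","category"
"R001",0.6467,0.6633,"chol_ch3","lipid"
"R002",0.6633,0.68,"chol_ch3","lipid"
"R003",0.68,0.6967,"chol_ch3","lipid"
"R004",0.6967,0.7133,"chol_ch3","lipid"
"R005",0.8467,0.8633,"lip_ch3","lipid"
"R006",0.8633,0.88,"lip_ch3","lipid"
"R007",0.88,0.8967,"lip_ch3","lipid"
"R008",0.8967,0.9133,"lip_ch3","lipid"
"R009",0.9253,0.9481,"isoleucine+leucine","metabolite"
"R010",0.9481,0.9709,"isoleucine+leucine","metabolite"
"R011",0.9796,1,"isoleucine+valine","metabolite"
"R012",1,1.0204,"isoleucine+valine","metabolite"
"R013",1.0296,1.0504,"valine","metabolite"
"R014",1.19,1.21,"beta-hydroxybutyrate","metabolite"
"R015",1.25,1.2716,"lactate+lip_ch2n+threonine","mixed"
"R016",1.2716,1.2932,"lactate+lip_ch2n+threonine","mixed"
"R017",1.2932,1.3148,"lactate+lip_ch2n+threonine","mixed"
"R018",1.3148,1.3363,"lactate+lip_ch2n+threonine","mixed"
"R019",1.4985,1.5195,"alanine","metabolite"
"R020",1.53,1.55,"lip_ch2ch2co","lipid"
"R021",1.55,1.57,"lip_ch2ch2co","lipid"
"R022",1.57,1.59,"lip_ch2ch2co","lipid"
"R023",1.59,1.61,"lip_ch2ch2co","lipid"
"R024",1.7054,1.72,"lysine","metabolite"
"R025",1.72,1.7346,"lysine","metabolite"
"R026",1.8857,1.9061,"acetate+arginine","metabolite"
"R027",1.9061,1.9265,"acetate+arginine","metabolite"
"R028",1.9833,2.0112,"glutamate+lip_allylic_nag","mixed"
"R029",2.0112,2.0391,"glutamate+lip_allylic_nag","mixed"
"R030",2.0391,2.067,"glutamate+lip_allylic_nag","mixed"
"R031",2.067,2.0949,"glutamate+lip_allylic_nag","mixed"
"R032",2.1248,2.14,"glutamine+methionine","metabolite"
"R033",2.14,2.1552,"glutamine+methionine","metabolite"
"R034",2.1933,2.2167,"acetoacetate+lip_ch2co","mixed"
"R035",2.2167,2.24,"acetoacetate+lip_ch2co","mixed"
"R036",2.24,2.2633,"acetoacetate+lip_ch2co","mixed"
"R037",2.2633,2.2867,"acetoacetate+lip_ch2co","mixed"
"R038",2.2918,2.31,"beta-hydroxybutyrate","metabolite"
"R039",2.31,2.3282,"beta-hydroxybutyrate","metabolite"
"R040",2.3352,2.3558,"glutamate+pyruvate","metabolite"
"R041",2.3558,2.3765,"glutamate+pyruvate","metabolite"
"R042",2.3875,2.4005,"succinate","metabolite"
"R043",2.4258,2.4454,"alpha-ketoglutarate+glutamine","metabolite"
"R044",2.4454,2.4649,"alpha-ketoglutarate+glutamine","metabolite"
"R045",2.5507,2.566,"citrate","metabolite"
"R046",2.566,2.5813,"citrate","metabolite"
"R047",2.6251,2.64,"methionine","metabolite"
"R048",2.64,2.6549,"methionine","metabolite"
"R049",2.6808,2.6993,"aspartate+citrate+lip_diallylic","mixed"
"R050",2.6993,2.7177,"aspartate+citrate+lip_diallylic","mixed"
"R051",2.7177,2.7361,"aspartate+citrate+lip_diallylic","mixed"
"R052",2.7361,2.7546,"aspartate+citrate+lip_diallylic","mixed"
"R053",2.7546,2.773,"aspartate+citrate+lip_diallylic","mixed"
"R054",2.773,2.7915,"aspartate+citrate+lip_diallylic","mixed"
"R055",2.7915,2.8099,"aspartate+citrate+lip_diallylic","mixed"
"R056",2.8099,2.8283,"aspartate+citrate+lip_diallylic","mixed"
"R057",2.8399,2.86,"asparagine","metabolite"
"R058",2.86,2.8801,"asparagine","metabolite"
"R059",2.9317,2.9476,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R060",2.9476,2.9634,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R061",2.9634,2.9792,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R062",2.9792,2.9951,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R063",2.9951,3.0109,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R064",3.0109,3.0267,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R065",3.0267,3.0426,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R066",3.0426,3.0584,"alpha-ketoglutarate+asparagine+creatine+creatinine+cysteine+lysine+lysyl","mixed"
"R067",3.0826,3.1,"tyrosine","metabolite"
"R068",3.1,3.1174,"tyrosine","metabolite"
"R069",3.2035,3.2165,"choline","metabolite"
"R070",3.2258,3.2436,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R071",3.2436,3.2614,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R072",3.2614,3.2792,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R073",3.2792,3.2969,"arginine+beta-D-glucopyranose+betaine+myo-inositol","metabolite"
"R074",3.3259,3.3541,"proline","metabolite"
"R075",3.4335,3.4465,"acetoacetate","metabolite"
"R076",3.5159,3.5441,"alpha-D-glucopyranose","metabolite"
"R077",3.5535,3.5665,"glycine","metabolite"
"R078",3.7915,3.8077,"alanine+serine","metabolite"
"R079",3.8077,3.8238,"alanine+serine","metabolite"
"R080",3.8238,3.84,"alanine+serine","metabolite"
"R081",3.84,3.8561,"alanine+serine","metabolite"
"R082",3.8935,3.9065,"betaine","metabolite"
"R083",3.9235,3.9365,"creatine","metabolite"
"R084",3.9445,3.96,"serine","metabolite"
"R085",3.96,3.9755,"serine","metabolite"
"R086",4.0485,4.0697,"creatinine+myo-inositol","metabolite"
"R087",4.092,4.1184,"lactate+proline","metabolite"
"R088",4.1184,4.1448,"lactate+proline","metabolite"
"R089",5.2214,5.2386,"alpha-D-glucopyranose","metabolite"
"R090",5.2667,5.2933,"lip_vinyl","lipid"
"R091",5.2933,5.32,"lip_vinyl","lipid"
"R092",5.32,5.3467,"lip_vinyl","lipid"
"R093",5.3467,5.3733,"lip_vinyl","lipid"
"R094",6.8888,6.9112,"tyrosine","metabolite"
"R095",7.0735,7.0865,"histidine","metabolite"
"R096",7.1788,7.2012,"tyrosine","metabolite"
"R097",7.2735,7.2865,"tryptophan","metabolite"
"R098",7.3193,7.3407,"phenylalanine","metabolite"
"R099",7.4053,7.42,"phenylalanine","metabolite"
"R100",7.42,7.4347,"phenylalanine","metabolite"
"R101",7.5291,7.5509,"tryptophan","metabolite"
"R102",7.7191,7.7409,"tryptophan","metabolite"
"R103",7.7835,7.7965,"histidine","metabolite"
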