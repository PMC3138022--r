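chemical,pd_mg_kg_day,source_code,molar_basis
"2,4,5-T",0.01,1,FALSE
"2,4,5-TP",0.008,1,FALSE
"2,4-D",0.005,2,FALSE
"2,4-DB",0.03,2,FALSE
"2,6 Diethylaniline",0.006,3,TRUE
"3-Hydroxycarbofuran",0.00006,2,TRUE
"Acetochlor",0.02,3,FALSE
"Acifluorfen",0.004,2,FALSE
"Alachlor",0.01,2,FALSE
"Aldicarb",0.00027,3,FALSE
"Aldicarb sulfone",0.00027,3,FALSE
"Aldicarb sulfoxide",0.00027,3,FALSE
"alpha-HCH",0.008,3,FALSE
"Atrazine",0.0019,2,FALSE
"Azinphos-methyl",0.00149,2,FALSE
"Benfluralin",0.005,2,FALSE
"Bentazon",0.03,2,FALSE
"Bromacil",0.1,2,FALSE
"Bromoxynil",0.015,2,FALSE
"Butylate",0.05,2,FALSE
"Carbaryl",0.01,2,FALSE
"Carbofuran",0.00006,2,FALSE
"Chloramben methyl ester",0.014,4,FALSE
"Chlorothalonil",0.02,2,FALSE
"Chlorpyrifos",0.00003,2,FALSE
"cis-Permethrin",0.25,2,FALSE
"Clopyralid",0.15,3,FALSE
"Cyanazine",0.00026,5,FALSE
"Dacthal",0.01,2,FALSE
"Dacthal monoacid",0.01,2,FALSE
"Diethyl atrazine",0.0018,2,TRUE
"Diazinon",0.0002,2,FALSE
"Dicamba",0.45,2,FALSE
"Dichlobenil",0.015,2,FALSE
"Dichlorprop",0.036,2,FALSE
"Dieldrin",0.00005,6,FALSE
"Dinoseb",0.001,1,FALSE
"Dinitro-o-cresol",0.004,6,FALSE
"Disulfoton",0.00013,2,FALSE
"Diuron",0.003,2,FALSE
"EPTC",0.0025,2,FALSE
"Ethalfluralin",0.04,2,FALSE
"Ethoprop",0.0001,2,FALSE
"Fluometuron",0.005,2,FALSE
"Fonofos",0.002,2,FALSE
"gamma-HCH",0.0003,1,FALSE
"Linuron",0.0077,2,FALSE
"Malathion",0.07,2,FALSE
"MCPA",0.0044,2,FALSE
"MCPB",0.015,2,FALSE
"Methiocarb",0.005,2,FALSE
"Methomyl",0.008,2,FALSE
"Metolachlor",0.1,2,FALSE
"Metribuzin",0.013,2,FALSE
"Molinate",0.001,3,FALSE
"Napropamide",0.12,2,FALSE
"Norflurazon",0.015,2,FALSE
"Oryzalin",0.12,2,FALSE
"Oxamyl",0.001,2,FALSE
"p,p'-DDE",0.0005,3,FALSE
"Parathion",0.006,7,FALSE
"Parathion-methyl",0.00002,2,FALSE
"Pebulate",0.0007,2,FALSE
"Pendimethalin",0.1,2,FALSE
"Phorate",0.00017,2,FALSE
"Picloram",0.2,2,FALSE
"Prometon",0.05,2,FALSE
"Pronamide",0.027,2,FALSE
"Propachlor",0.054,2,FALSE
"Propanil",0.009,2,FALSE
"Propargite",0.04,2,FALSE
"Propham",0.02,1,FALSE
"Propoxur",0.005,2,FALSE
"Simazine",0.0018,2,FALSE
"Tebuthiuron",0.07,2,FALSE
"Terbacil",0.013,2,FALSE
"Terbufos",0.00005,2,FALSE
"Thiobencarb",0.01,2,FALSE
"Triallate",0.025,2,FALSE
"Triclopyr",0.05,2,FALSE
"Trifluralin",0.024,2,FALSE
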