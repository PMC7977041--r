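stage	period	era	age_base	age_top
Fortunian	Cambrian	Paleozoic	538.8	529
Stage 2	Cambrian	Paleozoic	529	521
Stage 3	Cambrian	Paleozoic	521	514.5
Stage 4	Cambrian	Paleozoic	514.5	509
Wuliuan	Cambrian	Paleozoic	509	504.5
Drumian	Cambrian	Paleozoic	504.5	500.5
Guzhangian	Cambrian	Paleozoic	500.5	497
Paibian	Cambrian	Paleozoic	497	494.2
Jiangshanian	Cambrian	Paleozoic	494.2	489.5
Stage 10	Cambrian	Paleozoic	489.5	486.85
Tremadocian	Ordovician	Paleozoic	486.85	477.1
Floian	Ordovician	Paleozoic	477.1	471.3
Dapingian	Ordovician	Paleozoic	471.3	469.4
Darriwilian	Ordovician	Paleozoic	469.4	458.2
Sandbian	Ordovician	Paleozoic	458.2	452.8
Katian	Ordovician	Paleozoic	452.8	445.2
Hirnantian	Ordovician	Paleozoic	445.2	443.8
Rhuddanian	Silurian	Paleozoic	443.8	440.8
Aeronian	Silurian	Paleozoic	440.8	438.5
Telychian	Silurian	Paleozoic	438.5	433.4
Sheinwoodian	Silurian	Paleozoic	433.4	430.5
Homerian	Silurian	Paleozoic	430.5	427.4
Gorstian	Silurian	Paleozoic	427.4	425.6
Ludfordian	Silurian	Paleozoic	425.6	423
Pridoli	Silurian	Paleozoic	423	419.2
Lochkovian	Devonian	Paleozoic	419.2	410.8
Pragian	Devonian	Paleozoic	410.8	407.6
Emsian	Devonian	Paleozoic	407.6	393.3
Eifelian	Devonian	Paleozoic	393.3	387.7
Givetian	Devonian	Paleozoic	387.7	382.7
Frasnian	Devonian	Paleozoic	382.7	372.2
Famennian	Devonian	Paleozoic	372.2	358.9
Tournaisian	Carboniferous	Paleozoic	358.9	346.7
Visean	Carboniferous	Paleozoic	346.7	330.9
Serpukhovian	Carboniferous	Paleozoic	330.9	323.2
Bashkirian	Carboniferous	Paleozoic	323.2	315.2
Moscovian	Carboniferous	Paleozoic	315.2	307
Kasimovian	Carboniferous	Paleozoic	307	303.7
Gzhelian	Carboniferous	Paleozoic	303.7	298.9
Asselian	Permian	Paleozoic	298.9	293.52
Sakmarian	Permian	Paleozoic	293.52	290.1
Artinskian	Permian	Paleozoic	290.1	283.5
Kungurian	Permian	Paleozoic	283.5	273.01
Roadian	Permian	Paleozoic	273.01	266.9
Wordian	Permian	Paleozoic	266.9	264.28
Capitanian	Permian	Paleozoic	264.28	259.51
Wuchiapingian	Permian	Paleozoic	259.51	254.14
Changhsingian	Permian	Paleozoic	254.14	251.902
Induan	Triassic	Mesozoic	251.902	251.2
Olenekian	Triassic	Mesozoic	251.2	247.2
Anisian	Triassic	Mesozoic	247.2	242
Ladinian	Triassic	Mesozoic	242	237
Carnian	Triassic	Mesozoic	237	227
Norian	Triassic	Mesozoic	227	208.5
Rhaetian	Triassic	Mesozoic	208.5	201.4
Hettangian	Jurassic	Mesozoic	201.4	199.5
Sinemurian	Jurassic	Mesozoic	199.5	192.9
Pliensbachian	Jurassic	Mesozoic	192.9	184.2
Toarcian	Jurassic	Mesozoic	184.2	174.7
Aalenian	Jurassic	Mesozoic	174.7	170.9
Bajocian	Jurassic	Mesozoic	170.9	168.2
Bathonian	Jurassic	Mesozoic	168.2	165.3
Callovian	Jurassic	Mesozoic	165.3	161.5
Oxfordian	Jurassic	Mesozoic	161.5	154.8
Kimmeridgian	Jurassic	Mesozoic	154.8	149.2
Tithonian	Jurassic	Mesozoic	149.2	145
Berriasian	Cretaceous	Mesozoic	145	139.8
Valanginian	Cretaceous	Mesozoic	139.8	132.6
Hauterivian	Cretaceous	Mesozoic	132.6	125.77
Barremian	Cretaceous	Mesozoic	125.77	121.4
Aptian	Cretaceous	Mesozoic	121.4	113
Albian	Cretaceous	Mesozoic	113	100.5
Cenomanian	Cretaceous	Mesozoic	100.5	93.9
Turonian	Cretaceous	Mesozoic	93.9	89.8
Coniacian	Cretaceous	Mesozoic	89.8	86.3
Santonian	Cretaceous	Mesozoic	86.3	83.6
Campanian	Cretaceous	Mesozoic	83.6	72.1
Maastrichtian	Cretaceous	Mesozoic	72.1	66
Danian	Paleogene	Cenozoic	66	61.6
Selandian	Paleogene	Cenozoic	61.6	59.2
Thanetian	Paleogene	Cenozoic	59.2	56
Ypresian	Paleogene	Cenozoic	56	47.8
Lutetian	Paleogene	Cenozoic	47.8	41.2
Bartonian	Paleogene	Cenozoic	41.2	37.71
Priabonian	Paleogene	Cenozoic	37.71	33.9
Rupelian	Paleogene	Cenozoic	33.9	27.82
Chattian	Paleogene	Cenozoic	27.82	23.03
Aquitanian	Neogene	Cenozoic	23.03	20.44
Burdigalian	Neogene	Cenozoic	20.44	15.97
Langhian	Neogene	Cenozoic	15.97	13.82
Serravallian	Neogene	Cenozoic	13.82	11.63
Tortonian	Neogene	Cenozoic	11.63	7.246
Messinian	Neogene	Cenozoic	7.246	5.333
Zanclean	Neogene	Cenozoic	5.333	3.6
Piacenzian	Neogene	Cenozoic	3.6	2.58
Gelasian	Quaternary	Cenozoic	2.58	1.8
Calabrian	Quaternary	Cenozoic	1.8	0.774
Chibanian	Quaternary	Cenozoic	0.774	0.129
Late Pleistocene	Quaternary	Cenozoic	0.129	0.0117
Holocene	Quaternary	Cenozoic	0.0117	0
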