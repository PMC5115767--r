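residue,label,chain,resno,resname,kl,cmi,pmi,mobility,hinge,centrality,cp
1,A:1,A,1,ALA,0.37207924,0,0,0.23548094,FALSE,0,0.49642694
2,A:2,A,2,CYS,0.70455658,0,53.039416,0.20686412,FALSE,0.49011858,0.025145519
3,A:3,A,3,ASP,2.7101549,291.45979,71.050157,0.30753239,FALSE,0.09486166,0.021454297
4,A:4,A,4,GLU,0.45753878,0,42.980212,0.22136584,FALSE,0.086956522,0.095500131
5,A:5,A,5,PHE,0.56885866,0,10.685569,0.21939357,FALSE,0.27272727,0.0055071357
6,A:6,A,6,GLY,0.30818722,0,68.096337,0.26261083,FALSE,0.0079051383,0.032454123
7,A:7,A,7,HIS,2.6083081,182.24825,58.977558,0.98656957,FALSE,0.015810277,0.068966835
8,A:8,A,8,ILE,0.39078413,0,43.840828,0.44128422,FALSE,0.075098814,0.074039596
9,A:9,A,9,LYS,0.46888279,0,0,1,FALSE,0,0.48787314
10,A:10,A,10,LEU,0.30157786,0,0,0.062758574,TRUE,0.52173913,0.50249383
11,A:11,A,11,MET,0.53325236,0,6.9486033,0.10606151,FALSE,0.51383399,0.0066987401
12,A:12,A,12,ASN,0.51528478,6.6527594,94.80629,0.17284734,FALSE,0,0.0045431299
13,B:1,B,1,PRO,0.42538487,0,0,0.1075144,TRUE,0.52173913,0.50273142
14,B:2,B,2,GLN,0.55761972,0,55.062753,0.11966734,FALSE,0.39525692,0.055184087
15,B:3,B,3,ARG,1.9492993,297.50887,69.503744,0.1657207,FALSE,0.0079051383,0.021943333
16,B:4,B,4,SER,0.42570763,0,6.2507314,0.16841126,FALSE,0.1541502,0.0098697139
17,B:5,B,5,THR,0.6516749,0,39.495682,0.18940028,FALSE,0.14624506,0.0064423186
18,B:6,B,6,VAL,0.37685823,0,74.922698,0.25273712,FALSE,0.0079051383,0.012787651
19,B:7,B,7,TRP,0.75705048,0,55.294931,0.94857834,FALSE,0.11067194,0.019159284
20,B:8,B,8,TYR,1.9535554,173.09718,40.197011,0.40911464,FALSE,0.1027668,0.04553984
21,B:9,B,9,ALA,0.33964483,0,55.294931,0.97620872,FALSE,0,0.054694156
22,B:10,B,10,CYS,0.82375749,0,0,0.24844076,FALSE,0,0.49512675
23,B:11,B,11,ASP,0.36070738,0,5.7848947,0.21339637,FALSE,0.15810277,0.0057075323
24,B:12,B,12,GLU,0.40865827,0,93.880577,0.2960531,FALSE,0,0.014242883
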