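mode,eigenvalue,zero_mode,collectivity
1,1.4210855e-14,TRUE,1
2,0.55837977,FALSE,0.85317375
3,2.2705295,FALSE,0.57195599
4,2.6570938,FALSE,0.32947102
5,2.6877943,FALSE,0.33843996
6,2.7832008,FALSE,0.35577658
7,3.6715978,FALSE,0.57080395
8,4.2546084,FALSE,0.3842757
9,5.5525895,FALSE,0.13792408
10,5.5679638,FALSE,0.13526824
11,6,FALSE,0.16666667
12,6.2003519,FALSE,0.23497157
13,6.9344948,FALSE,0.36379366
14,7.4511796,FALSE,0.31006524
15,7.778885,FALSE,0.31923747
16,8.1396951,FALSE,0.4047774
17,8.3348745,FALSE,0.43039109
18,8.6612299,FALSE,0.25457899
19,9.2682335,FALSE,0.17526776
20,9.7607555,FALSE,0.23570455
21,10.411746,FALSE,0.2563283
22,11.121564,FALSE,0.13680779
23,11.725592,FALSE,0.23966113
24,12.207641,FALSE,0.13386673
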