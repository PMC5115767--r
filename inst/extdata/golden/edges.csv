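i,j,r,weight,label_i,label_j
1,2,0.30036792,1.2027471,A:1,A:2
1,4,0.34014102,1.078395,A:1,A:4
2,3,0.47478009,0.74490354,A:2,A:3
2,5,0.35427316,1.037687,A:2,A:5
2,11,0.29972877,1.2048773,A:2,A:11
3,6,0.2265838,1.4846404,A:3,A:6
3,12,0.30202846,1.197234,A:3,A:12
4,5,0.29385359,1.2246736,A:4,A:5
4,7,0.4137957,0.8823829,A:4,A:7
5,6,0.28935849,1.2400889,A:5,A:6
5,8,0.25177099,1.3792354,A:5,A:8
6,9,0.17621177,1.7360688,A:6,A:9
7,8,0.22599618,1.4872372,A:7,A:8
8,9,0.37455522,0.98201603,A:8,A:9
10,11,0.26384485,1.332394,A:10,A:11
10,13,0.19325388,1.6437505,A:10,B:1
11,12,0.25626644,1.3615376,A:11,A:12
13,14,0.31722693,1.1481379,B:1,B:2
13,16,0.31360966,1.1596062,B:1,B:4
14,15,0.39199572,0.93650435,B:2,B:3
14,17,0.36443534,1.0094061,B:2,B:5
14,23,0.3577597,1.0278938,B:2,B:11
15,18,0.19238532,1.648255,B:3,B:6
15,24,0.17391684,1.749178,B:3,B:12
16,17,0.34113275,1.0754836,B:4,B:5
16,19,0.48015585,0.73364454,B:4,B:7
17,18,0.29052659,1.2360602,B:5,B:6
17,20,0.44726941,0.80459416,B:5,B:8
18,21,0.38844565,0.94560201,B:6,B:9
19,20,0.70672201,0.34711789,B:7,B:8
20,21,0.26678427,1.3213149,B:8,B:9
22,23,0.29652551,1.215622,B:10,B:11
23,24,0.3224232,1.1318903,B:11,B:12
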