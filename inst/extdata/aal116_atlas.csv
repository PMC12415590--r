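# 116-region AAL-style parcellation with a conventional seven-area grouping.
# The area assignment is a packaged convention for summarising edge distributions;
# substitute your own atlas file to change the parcellation or grouping.
index,name,area
1,PreCG.L,frontal
2,PreCG.R,frontal
3,SFGdor.L,frontal
4,SFGdor.R,frontal
5,ORBsup.L,frontal
6,ORBsup.R,frontal
7,MFG.L,frontal
8,MFG.R,frontal
9,ORBmid.L,frontal
10,ORBmid.R,frontal
11,IFGoperc.L,frontal
12,IFGoperc.R,frontal
13,IFGtriang.L,frontal
14,IFGtriang.R,frontal
15,ORBinf.L,frontal
16,ORBinf.R,frontal
17,ROL.L,frontal
18,ROL.R,frontal
19,SMA.L,frontal
20,SMA.R,frontal
21,OLF.L,frontal
22,OLF.R,frontal
23,SFGmed.L,frontal
24,SFGmed.R,frontal
25,ORBsupmed.L,frontal
26,ORBsupmed.R,frontal
27,REC.L,frontal
28,REC.R,frontal
29,INS.L,limbic
30,INS.R,limbic
31,ACG.L,limbic
32,ACG.R,limbic
33,DCG.L,limbic
34,DCG.R,limbic
35,PCG.L,limbic
36,PCG.R,limbic
37,HIP.L,limbic
38,HIP.R,limbic
39,PHG.L,limbic
40,PHG.R,limbic
41,AMYG.L,limbic
42,AMYG.R,limbic
43,CAL.L,occipital
44,CAL.R,occipital
45,CUN.L,occipital
46,CUN.R,occipital
47,LING.L,occipital
48,LING.R,occipital
49,SOG.L,occipital
50,SOG.R,occipital
51,MOG.L,occipital
52,MOG.R,occipital
53,IOG.L,occipital
54,IOG.R,occipital
55,FFG.L,temporal
56,FFG.R,temporal
57,PoCG.L,parietal
58,PoCG.R,parietal
59,SPG.L,parietal
60,SPG.R,parietal
61,IPL.L,parietal
62,IPL.R,parietal
63,SMG.L,parietal
64,SMG.R,parietal
65,ANG.L,parietal
66,ANG.R,parietal
67,PCUN.L,parietal
68,PCUN.R,parietal
69,PCL.L,frontal
70,PCL.R,frontal
71,CAU.L,subcortical
72,CAU.R,subcortical
73,PUT.L,subcortical
74,PUT.R,subcortical
75,PAL.L,subcortical
76,PAL.R,subcortical
77,THA.L,subcortical
78,THA.R,subcortical
79,HES.L,temporal
80,HES.R,temporal
81,STG.L,temporal
82,STG.R,temporal
83,TPOsup.L,temporal
84,TPOsup.R,temporal
85,MTG.L,temporal
86,MTG.R,temporal
87,TPOmid.L,temporal
88,TPOmid.R,temporal
89,ITG.L,temporal
90,ITG.R,temporal
91,CRBLCrus1.L,cerebellum
92,CRBLCrus1.R,cerebellum
93,CRBLCrus2.L,cerebellum
94,CRBLCrus2.R,cerebellum
95,CRBL3.L,cerebellum
96,CRBL3.R,cerebellum
97,CRBL45.L,cerebellum
98,CRBL45.R,cerebellum
99,CRBL6.L,cerebellum
100,CRBL6.R,cerebellum
101,CRBL7b.L,cerebellum
102,CRBL7b.R,cerebellum
103,CRBL8.L,cerebellum
104,CRBL8.R,cerebellum
105,CRBL9.L,cerebellum
106,CRBL9.R,cerebellum
107,CRBL10.L,cerebellum
108,CRBL10.R,cerebellum
109,Vermis12,cerebellum
110,Vermis3,cerebellum
111,Vermis45,cerebellum
112,Vermis6,cerebellum
113,Vermis7,cerebellum
114,Vermis8,cerebellum
115,Vermis9,cerebellum
116,Vermis10,cerebellum
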