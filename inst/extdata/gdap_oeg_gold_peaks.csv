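mz,formula,category
15.02,CH3,Hydrocarbon
18.04,NH4,GDAP
22.99,Na,Salt
27.02,C2H3,Hydrocarbon
28.03,C2H4,Hydrocarbon
29.00,CHO,OEG/SAM
29.04,C2H5,Hydrocarbon
30.04,CH4N,GDAP
38.96,K,Salt
41.04,C3H5,Hydrocarbon
43.02,C2H3O,OEG/SAM
44.05,C2H6N,GDAP
44.98,CHS,OEG/SAM
45.03,C2H5O,OEG/SAM
55.02,C3H3O,OEG/SAM
56.03,C3H4O,OEG/SAM
56.06,C3H6N,GDAP
59.00,C2H3S,OEG/SAM
59.05,C3H7O,GDAP
60.06,C2H6NO,GDAP
61.01,C2H5S,OEG/SAM
69.04,C3H5N2,GDAP
70.07,C4H8N,GDAP
72.09,C4H10N,GDAP
75.04,C3H7O2,OEG/SAM
84.05,C4H6NO,GDAP
84.09,C5H10N,GDAP
99.06,C5H7O2,OEG/SAM
110.09,C6H10N2,GDAP
116.05,C5H8O3,OEG/SAM
196.97,Au,Gold
225.00,AuC2H4,Gold
256.98,AuC2H4S,Gold
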