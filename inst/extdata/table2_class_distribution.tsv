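class_id	name	source	n_formulas	percentage
1	Blood and lymph diseases	NCBI	201	6.41
2	Cancers	NCBI	32	1.02
3	The digestive system	NCBI	457	14.56
4	Ear, nose, and throat	NCBI	2	0.06
5	Diseases of the eye	NCBI	1	0.03
6	Female-specific diseases	NCBI	382	12.17
7	Glands and hormones	NCBI	0	NA
8	The heart and blood vessels	NCBI	57	1.82
9	Diseases of the immune system	NCBI	22	0.70
10	Male-specific diseases	NCBI	17	0.54
11	Muscle and bone	NCBI	649	20.68
12	Neonatal diseases	NCBI	0	NA
13	The nervous system	NCBI	32	1.02
14	Nutritional and metabolic diseases	NCBI	576	18.36
15	Respiratory diseases	NCBI	313	9.97
16	Skin and connective tissue	NCBI	163	5.19
17	The urinary system	study-added	90	2.87
18	Mental and behavioral disorders	study-added	21	0.67
multi	Multiple disease classes	NA	119	3.79
unclassified	Unclassified	NA	4	0.13
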