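entry_id	disease	class_ids
1	Abdominal pain	3
2	Abdominal pain, diarrhea	3
3	Acne	16
4	Acne, skin problems (cosmetics)	16
5	Amenorrhoea, dysmenorrhea	6
6	Amenorrhoea, irregular menstruation	6
7	Anaemia	1
8	Appendicitis, urinary tract infection, tonsillitis	3
9	Arthralgia	11
10	Arthralgia, arthritis	11
11	Asthma	15
12	Benign prostatic hyperplasia (Bph)	10
13	Breast disorder	6
14	Bromhidrosis	16
15	Bronchitis	15
16	Cancer	2
17	Cancer pain	2
18	Cancer, inflammation	2
19	Colic abdomen, bloating (in infant)	3
20	Common cold	15
21	Common cold, dyspepsia, insect bites	15,3,16
22	Common cold, influenza	15
23	Cough	15
24	Degenerative disease	14
25	Dermatitis, urticaria, erythema	16
26	Diabetes	14
27	Diabetic gangrene	16
28	Diarrhea	3
29	Diarrhea, abdominal pain	3
30	Diseases of the eye	5
31	Disorders in pregnancy	6
32	Dysmenorrhea	6
33	Dysmenorrhea, irregular menstruation	6
34	Dysmenorrhea, menstrual syndrome	6
35	Dyspepsia	3
36	Dyspnoea	15
37	Dyspnoea, cough, orthopnoea	15
38	Fatigue	11
39	Fatigue, anaemia, loss appetite	1
40	Fatigue, lack of sexual function	6
41	Fatigue, low back pain	11
42	Fatigue, myalgia, arthralgia	11
43	Fatigue, osteoarthritis	11
44	Fertility problem	6,10
45	Fever	0
46	Gastritis, gastric ulcer	3
47	Haemorrhoids	1
48	Headache	13
49	Heart diseases	8
50	Heartburn	3,8
51	Hepatitis, other diseases of liver	3
52	Hypercholesterolaemia	14
53	Hypertension	8
54	Hypertension, diabetes	14
55	Hypertension, hypercholesterolaemia	14
56	Hyperuricemia	1
57	Immunodefficiency	9
58	Indigestion (K.30)	3
59	Indigestion, lose appetite	3
60	Infertility	6,10
61	Irregular menstruation, menstruation syndrome	6
62	Kidney diseases	17
63	Lactation problems	6
64	Leukorrhoea (Vaginalis)	6
65	Leukorrhoea (Vaginalis), dysmenorrhoea	6
66	Lose appetite	3
67	Lose appetite, underweight	14
68	Low back pain, myalgia, arthralgia	11
69	Low back pain, myalgia, constipation	11
70	Low back pain, urinary tract infection	17
71	Lung diseases	15
72	Malaise and Fatigue	11
73	Malaise and Fatigue, Constipation	11
74	Malaise and Fatigue, Fertility Problems	10,11
75	Malaise and Fatigue, Low Back Pain	11
76	Malaise and Fatigue, Sexual Dysfunction	11,6,10
77	Malaise and Fatigue, Skin Problems (Cosmetics)	16
78	Malaria, anaemia	1
79	Meno-metrorrhagia	6
80	Menopausal syndrome	6
81	Menopause/menstrual syndrome, leukorrhoea (vaginalis)	6
82	Menstrual syndrome	6
83	Menstrual syndrome, fatigue	6
84	Migraine	13
85	Mood disorder	18
86	Myalgia, arthralgia	11
87	Nausea/vomiting of pregnancy	6
88	Osteoarthritis	11
89	Osteoarthritis, fatigue	11
90	Overweight, obesity	14
91	Paralysis	13
92	Post partum syndrome	6
93	Prevent from overweight	14
94	Respiratory infection due to smoking	15
95	Respiratory tract infection	15
96	Rheumatoid arthritis, gout	11
97	Secondary amenorrhea	6
98	Secondary amenorrhea, irregular menstruation	6
99	Sexual dysfunction, fatigue	6,10
100	Skin diseases	16
101	Skin problems (cosmetics)	16
102	Sleeping and Mood Disorders	18
103	Sleeping disorders	18
104	Stomatitis	3
105	Stomatitis, gingivitis, tonsilitis	3
106	Stone in kidney (N20.0)	17
107	Stone in kidney (N20.0), urinary bladder stone (N21.0)	17
108	Tonsilitis	4
109	Tonsilofaringitis	4
110	Toothache	13
111	Typhoid, dyspepsia	3
112	Ulcer of anus and rectum	3
113	Underweight, lose appetite	3
114	Urinary tract infection (urethritis)	17
115	Vaginal discharges	6
116	Vaginal diseases	6
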