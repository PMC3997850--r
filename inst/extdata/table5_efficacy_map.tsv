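class_id	class_name	efficacy_ids
1	Blood and lymph diseases	E7
2	Cancers	E7
3	The digestive system	E4,E7
4	Ear, nose, and throat	E7
5	Diseases of the eye	E7
6	Female-specific diseases	E5
7	Glands and hormones	E7
8	The heart and blood vessels	E7
9	Diseases of the immune system	E7
10	Male-specific diseases	E6
11	Muscle and bone	E6
12	Neonatal diseases	E7
13	The nervous system	E7
14	Nutritional and metabolic diseases	E2,E4
15	Respiratory diseases	E8,E7
16	Skin and connective tissue	E9
17	The urinary system	E1
18	Mental and behavioural disorders	E3
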