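label	count	denominator	denominator_kind	sex_restriction	gi_member
Overall cancer	75037	367703	all	none	0
Breast	13666	198904	relevant_sex	female	0
Prostate	7872	168799	relevant_sex	male	0
Lung	2838	367703	all	none	0
Bowel	5486	367703	all	none	1
Melanoma	4869	367703	all	none	0
Non-Hodgkin's lymphoma	2296	367703	all	none	0
Kidney	1310	367703	all	none	0
Head/neck	1615	367703	all	none	0
Brain	810	367703	all	none	0
Bladder	2588	367703	all	none	0
Pancreas	1264	367703	all	none	1
Uterus	1931	198904	relevant_sex	female	0
Leukaemia	1403	367703	all	none	0
Esophagus	843	367703	all	none	1
Ovaries	1520	198904	relevant_sex	female	0
Gastric	736	367703	all	none	1
Liver	324	367703	all	none	1
Myeloma	656	367703	all	none	0
Thyroid	375	367703	all	none	0
Biliary	387	367703	all	none	1
Cervix	1928	198904	relevant_sex	female	0
Testes	735	168799	relevant_sex	male	0
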