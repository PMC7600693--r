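# Published screen: genes present in all human-adapted Bacteroides genomes and
# absent (<50% amino-acid similarity) from all chicken-adapted genomes.
# Similarity columns: percent amino-acid similarity of the best hit in each
# human-adapted genome against the B. dorei An41 reference (reference = 100).
# n_expr: strain x condition cells with >=1 PSM (max 55 = 5 strains x 11
# conditions); n.e. = not expressed. abundance_pct: mean percent of total
# protein during in vitro growth.
gene	An41	An109	An161	An43	An67	An878	An905	n_expr	abundance_pct
Glutamate decarboxylase	100	84.23	84.02	84.94	84.73	83.61	97.93	55	1.054
Glucose-6-phosphate 1-dehydrogenase	100	58.06	58.47	58.84	60.44	58.27	97.37	53	0.090
6-phosphogluconate dehydrogenase, decarboxylating	100	61.65	61.23	61.6	60.55	62.5	95.4	50	0.206
Pirin	100	58.12	67.52	59.4	56.84	66.67	92.74	47	0.109
Transaldolase	100	85.78	86.24	85.78	85.78	86.24	98.62	44	0.084
Nitroreductase family protein	100	64.29	63.78	60.71	61.73	66.33	95.02	32	0.039
Endonuclease IV	100	75.95	74.05	79.01	78.46	74.05	96.18	29	0.043
Osmosensitive K+ channel histidine kinase KdpD	100	77.13	76.6	78.49	80.65	78.07	98.93	26	0.015
Integral membrane protein	100	58.83	58.11	56.9	57.77	58.21	97.36	12	0.029
Glutamate/gamma-aminobutyrate antiporter	100	83.05	83.47	80	80.62	83.47	98.12	12	0.029
Glutamine synthetase type I	100	83.8	83.8	81	82	86.44	97.98	10	0.073
YbbM seven transmembrane helix protein	100	74.24	73.48	73.21	69.81	74.62	98.87	9	0.018
probable uroporphyrin-III c-methyltransferase	100	58.47	60.17	56.78	61.02	57.27	97.46	5	0.009
FIG00936253: hypothetical protein	100	78.35	77.32	78.35	82.72	80.41	99.07	3	0.011
Imidazolonepropionase	100	70.05	70.39	65.78	65.53	69.86	98.55	3	0.006
Cell division protein MraZ	100	68.42	67.67	60.87	67.67	68.42	97.83	3	0.006
Formiminotetrahydrofolate cyclodeaminase	100	54.68	56.65	55.96	57.14	55.83	98.55	2	0.005
Urocanate hydratase	100	84.98	84.07	81.03	81.54	84.94	97.59	2	0.007
FIG00406657: hypothetical protein	100	61.92	61.67	59.71	58.54	60.93	97.31	2	0.007
Glutamate formiminotransferase	100	79.33	79.33	85.19	87.12	82.67	98.98	1	0.002
COG1272: Predicted membrane protein hemolysin III	100	58.69	58.69	55.29	54.81	59.81	98.58	1	0.002
Potassium-transporting ATPase A chain	100	85.74	85.92	85.74	85.21	85.21	99.12	1	0.007
Potassium-transporting ATPase C chain	100	77.13	76.6	81.82	79.03	77.25	96.83	1	0.024
D-alanyl-D-alanine dipeptidase	100	68.56	66.67	66.98	70.65	65.7	98.19	1	0.002
FIG00407539: hypothetical protein	100	68.12	70.44	56.59	59.02	67.79	95.69	n.e.	n.e.
Cold shock protein CspA	100	50	50	51.68	58.11	53.69	99.32	n.e.	n.e.
FIG00407264: hypothetical protein	100	70	68.82	63.74	62.35	68.82	99.42	n.e.	n.e.
FIG00412566: hypothetical protein	100	56.85	56.85	54.58	54.47	55.37	95.53	n.e.	n.e.
membrane protein ykgB	100	70.31	70.83	87.11	90.21	70.31	95.9	n.e.	n.e.
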