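mutation	gene	aa_change	heteroplasmy	matches_genbank	cons_eukaryotes	cons_vertebrates	cons_mammals	polyphen2	sift	families	association	prior_occurrences
m.3700G>A	MT-ND1	p.A132T	-	0	79.22	93.52	98.73	benign	not tolerated	F1,F2	strict	0
m.3733G>A	MT-ND1	p.E143K	-/+	1	99.35	99.07	98.73	possibly damaging	not tolerated	F5,F14	strict	1
m.3733G>C	MT-ND1	p.E143Q	+ (78%)	0	99.35	99.07	98.73	probably damaging	not tolerated	F9	strict	0
m.4171C>A	MT-ND1	p.L289M	+ (80%)	0	60.39	84.26	100.00	probably damaging	tolerated	F13	strict	4
m.10663T>C	MT-ND4L	p.V65A	-	0	79.33	91.73	99.61	possibly damaging	tolerated	F16	strict	5
m.14459G>A	MT-ND6	p.A72V	-	1	54.03	72.29	100.00	probably damaging	not tolerated	F8	lhon_plus	5
m.14482C>A	MT-ND6	p.M64I	-/+	0	64.52	75.90	58.14	probably damaging	not tolerated	F10,F15	strict	2
m.14495A>G	MT-ND6	p.L60S	+ (41%)	0	79.03	100.00	100.00	probably damaging	not tolerated	F3	strict	2
m.14568C>T	MT-ND6	p.G36S	-/+ (60-90%)	2	34.68	51.81	100.00	probably damaging	not tolerated	F4,F6,F7,F11,F12	strict	1
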