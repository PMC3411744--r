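gene	start	end	strand	product
MT-TF	577	647	+	tRNA
MT-RNR1	648	1601	+	rRNA
MT-TV	1602	1670	+	tRNA
MT-RNR2	1671	3229	+	rRNA
MT-TL1	3230	3304	+	tRNA
MT-ND1	3307	4260	+	protein
MT-TI	4263	4331	+	tRNA
MT-TM	4402	4469	+	tRNA
MT-ND2	4470	5510	+	protein
MT-CO1	5904	7445	+	protein
MT-CO2	7586	8269	+	protein
MT-ATP8	8366	8524	+	protein
MT-ATP6	8527	9204	+	protein
MT-CO3	9207	9989	+	protein
MT-ND3	10059	10403	+	protein
MT-ND4L	10470	10766	+	protein
MT-ND4	10767	12137	+	protein
MT-ND5	12337	14148	+	protein
MT-ND6	14149	14673	-	protein
MT-CYB	14747	15886	+	protein
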