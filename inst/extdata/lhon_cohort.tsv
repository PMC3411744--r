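sample_id	origin	phenotype	haplogroup	variants	rare_variants	accession
F1	Italy	affected	H	3700,13759	3700	JN415470
F2	Germany	affected	H26a	3700	3700	JN415471
F3	Italy	affected	H66	14495	14495	JN415472
F4	Germany	affected	H1c1	14568	14568	JN415473
F5	Italy	affected	H10	3733,9091	3733	JN415474
F6	Italy	affected	U6a1a1	4172A,7805,14568,14766,14927,15221	14568	EF064318.1
F7	France	affected	K1a	7299,9055,10398,13759,14568,14766,14798	14568	JN415475
F8	Italy	affected	J1c3	4216,10398,13708,13934,14459,14766,14798,15452A	14459	JN415476
F9	Germany	affected	J1c3e1	3733C,4216,10398,13145,13708,13934,14502,14766,14798,15452A	3733C	JN415477
F10	Italy	affected	J1c	4216,10398,13708,14482A,14766,14798,15452A	14482A	JN415478
F11	France	affected	J1c2e	4216,10398,13708,14568,14766,14798,15452A	14568	JN415479
F12	Germany	affected	J1c2	4216,10398,13708,14325,14568,14766,14798,15452A	14568	JN415480
F13	France	affected	J2b1	4171A,4216,7632,10398,13708,14766,15257,15452A,15812	4171A	JN415481
F14	Italy	affected	X2b	3733,7859,8393,11084,13708,13966,14766	3733	JN415482
F15	Germany	affected	I5a	5074,10398,13780,14482A,14766	14482A	JN415483
F16	France	affected	L2a1	8701,9053,10398,10663,14766	10663	JN415484
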