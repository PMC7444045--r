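rt	junction	chrom1	pos1	side1	chrom2	pos2	side2	ct	type	h	ins_len	hom_ext1	hom_ext2
t2_4	5to5	2	4983988	head	4	81209353	head	5to5	MICROHOMOLOGY	2	0	0	2
t2_4	3to3	2	4983990	tail	4	81209358	tail	3to3	BLUNT	0	0	0	0
t6_8	5to3	6	27901326	head	8	1266615	tail	5to3	MICROHOMOLOGY	3	0	3	0
t6_8	3to5	6	27901330	tail	8	1266598	head	3to5	BLUNT	0	0	0	0
t7_14	5to3	7	118889969	head	14	49733352	tail	5to3	MICROINSERTION	0	12	0	0
t7_14	3to5	7	118889973	tail	14	49733364	head	3to5	BLUNT	0	0	0	0
t1_16	5to3	1	97320431	head	16	23532204	tail	5to3	MICROINSERTION	0	15	0	0
t1_16	3to5	1	97320436	tail	16	23532186	head	3to5	MICROINSERTION	0	20	0	0
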