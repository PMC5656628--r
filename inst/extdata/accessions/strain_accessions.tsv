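#
# Chloropicophyceae / prasinophyte clade VII strains: GenBank accessions
# for the nuclear 18S rRNA, plastid 16S rRNA and rDNA ITS region, with
# clade assignments (lineage A = Chloropicon, B = Chloroparvula,
# C = Picocystis). Transcribed from the culture-collection strain records;
# a few ITS ids appear twice in the printed source (flagged "dup") and
# should be verified against GenBank when fetched. RCC1021's ITS strain
# was lost (no ITS accession).
#
id	clade	acc_18s	acc_16s	acc_its	note
RCC712	A1	KU843579	LN735451	MF077495
RCC713	A1	KU843580	LN735452	MF077496
RCC719	A1	KU843582	LN735454	MF077497
RCC997	A1	KT860935	LN735515	MF077503
RCC998	A1	KF422632	LN735516	MF077504	type strain
RCC138	A2	KT860872	LN735241	MF077488
RCC15	A2	U40921	AY702121	HE610139	type strain; 16S also FN563080
RCC717	A2	KU843581	LN735453	MF077479
NIES-3671	A3	KU843576	KU843562	MF077477
RCC1019	A3	KU843588	LN735204	MF077506
RCC1032	A3	KU843590	LN735207	MF077507
RCC1043	A3	KU843591	LN735210	MF077508	dup ITS with RCC287
RCC287	A3	AY425302	AY702147	MF077508	type strain; dup ITS with RCC1043
RCC297	A3	KT860659	LN735413	MF077491
RCC857	A3	KU843585	LN735471	MF077500
NIES-2755	A4	KF422627	LN735348	MF077511
NIES-3667	A4	KU843594	KU843566	MF077514
NIES-3668	A4	KU843573	KU843559	MF077513	dup ITS with RCC3368
NIES-3670	A4	KU843575	KU843561	MF077487
RCC1124	A4	KU843592	LN735219	MF077509
RCC1871	A4	KF899840	LN735295	MF077510	type strain
RCC4429	A4	KU843597	KU843571	MF077517
RCC4430	A4	KU843598	KU843572	MF077518
RCC722	A4	KU843583	KU843566	MF077498
RCC726	A4	KU843584	LN735455	MF077499
RCC917	A4	FJ997211	LN735488	MF077501
RCC1021	A5	KU843589	LN735205		ITS strain lost
RCC19	A5	KT860855	KU843563	MF077478
RCC227	A5	KT860875	KU843564	MF077489
RCC3375	A5	KF899843	KU843569	MF077516
RCC700	A5	KU843578	LN735441	MF077493
RCC701	A5	KF899839	KU843565	MF077494
RCC856	A5	KF422631	LN735470	MF077480	type strain
RCC887	A5	MF077474	MF077471	MF077481
RCC4434	A6	KU843599	MF077472	MF077519
RCC3374	A7	KU843595	KU843568	MF077515	type strain
RCC3368	A	MF077475	LN735423	MF077513	solitary branch; dup ITS with NIES-3668
RCC3376	A	KU843596	KU843570	MF077483	solitary branch
RCC996	A	KU843586	LN735514	MF077502	solitary branch; dup ITS with NIES-3669
NIES-3669	B1	KU843574	KU843560	MF077502	type strain; dup ITS with RCC996
NIES-2756	B2	KU843593	LN735349	MF077512
RCC696	B2	KU843577	LN735439	MF077492
RCC999	B2	KU843587	LN735517	MF077505
RCC4572	B3	MF077476	MF077473
NIES-2758	B	KF422628	LN735350	MF077482	type strain; solitary branch
RCC3402	C	FR865649	AB491631	HE610138	Picocystis salinarum outgroup
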