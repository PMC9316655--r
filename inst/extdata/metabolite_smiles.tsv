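name	smiles	inchikey	formula	monoisotopic_mass
glucose	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	WQZGKKKJIJFFOK-UHFFFAOYSA-N	C6H12O6	180.0634
fructose	OCC1(O)OC[C@@H](O)[C@@H](O)[C@@H]1O	LKDRXBCSQODPBY-UHFFFAOYSA-N	C6H12O6	180.0634
alanine	C[C@@H](N)C(=O)O	QNAYBMKLOCPYGJ-UHFFFAOYSA-N	C3H7NO2	89.0477
glycine	NCC(=O)O	DHMQDGOQFOQNFH-UHFFFAOYSA-N	C2H5NO2	75.032
serine	OC[C@@H](N)C(=O)O	MTCFGRXMJLQNBG-UHFFFAOYSA-N	C3H7NO3	105.0426
leucine	CC(C)C[C@@H](N)C(=O)O	ROHFNLRQFUQHCH-UHFFFAOYSA-N	C6H13NO2	131.0946
phenylalanine	N[C@@H](Cc1ccccc1)C(=O)O	COLNVLDHVKWLRT-UHFFFAOYSA-N	C9H11NO2	165.079
tyrosine	N[C@@H](Cc1ccc(O)cc1)C(=O)O	OUYCCCASQSFEME-UHFFFAOYSA-N	C9H11NO3	181.0739
tryptophan	N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O	QIVBCDIJIAJPQS-UHFFFAOYSA-N	C11H12N2O2	204.0899
glutamate	N[C@@H](CCC(=O)O)C(=O)O	WHUUTDBJXJRKMK-UHFFFAOYSA-N	C5H9NO4	147.0532
glutamine	N[C@@H](CCC(N)=O)C(=O)O	ZDXPYRJPNDTMRX-UHFFFAOYSA-N	C5H10N2O3	146.0691
arginine	N[C@@H](CCCNC(=N)N)C(=O)O	ODKSFYDXXFIFQN-UHFFFAOYSA-N	C6H14N4O2	174.1117
lysine	NCCCC[C@@H](N)C(=O)O	KDXKERNSBIXSRK-UHFFFAOYSA-N	C6H14N2O2	146.1055
citrate	OC(=O)CC(O)(CC(=O)O)C(=O)O	KRKNYBCHXYNGOX-UHFFFAOYSA-N	C6H8O7	192.027
succinate	OC(=O)CCC(=O)O	KDYFGRWQOYBRFD-UHFFFAOYSA-N	C4H6O4	118.0266
fumarate	OC(=O)/C=C/C(=O)O	VZCYOOQTPOCHFL-OWOJBTEDSA-N	C4H4O4	116.011
malate	O[C@@H](CC(=O)O)C(=O)O	BJEPYKJPYRNKOW-UHFFFAOYSA-N	C4H6O5	134.0215
pyruvate	CC(=O)C(=O)O	LCTONWCANYUPML-UHFFFAOYSA-N	C3H4O3	88.016
lactate	C[C@H](O)C(=O)O	JVTAAEKCZFNVCJ-UHFFFAOYSA-N	C3H6O3	90.0317
citrulline	N[C@@H](CCCNC(N)=O)C(=O)O	RHGKLRLOHDJJDR-UHFFFAOYSA-N	C6H13N3O3	175.0957
ornithine	NCCC[C@@H](N)C(=O)O	AHLPHDHHMVZTML-UHFFFAOYSA-N	C5H12N2O2	132.0899
taurine	NCCS(=O)(=O)O	XOAAWQZATWQOTB-UHFFFAOYSA-N	C2H7NO3S	125.0147
creatinine	CN1CC(=O)N=C1N	DDRJAANPRJIHGJ-UHFFFAOYSA-N	C4H7N3O	113.0589
creatine	CN(CC(=O)O)C(=N)N	CVSVTCORWBXHQV-UHFFFAOYSA-N	C4H9N3O2	131.0695
uricacid	O=c1[nH]c2[nH]c(=O)[nH]c2c(=O)[nH]1	LEHOTFFKMJEONL-UHFFFAOYSA-N	C5H4N4O3	168.0283
hypoxanthine	O=c1[nH]cnc2nc[nH]c12	FDGQSTZJBFJUBT-UHFFFAOYSA-N	C5H4N4O	136.0385
adenine	Nc1ncnc2[nH]cnc12	GFFGJBXGBJISGV-UHFFFAOYSA-N	C5H5N5	135.0545
adenosine	Nc1ncnc2c1ncn2[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O	OIRDTQYFTABQOQ-UHFFFAOYSA-N	C10H13N5O4	267.0968
inosine	O=c1[nH]cnc2c1ncn2[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O	UGQMRVRMYYASKQ-UHFFFAOYSA-N	C10H12N4O5	268.0808
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	RYYVLZVUVIJVGH-UHFFFAOYSA-N	C8H10N4O2	194.0804
cholesterol	C[C@H](CCCC(C)C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C	HVYWMOMLDIMFJA-UHFFFAOYSA-N	C27H46O	386.3549
tricarballylate	OC(=O)CC(CC(=O)O)C(=O)O	KQTIIICEAUMSDG-UHFFFAOYSA-N	C6H8O6	176.0321
niacin	OC(=O)c1cccnc1	PVNIIMVLHYAWGP-UHFFFAOYSA-N	C6H5NO2	123.032
pantothenate	CC(C)(CO)[C@@H](O)C(=O)NCCC(=O)O	GHOKWGTUZJEAQD-UHFFFAOYSA-N	C9H17NO5	219.1107
carnitine	C[N+](C)(C)C[C@H](O)CC(=O)[O-]	PHIQHXFUZVPYII-UHFFFAOYSA-N	C7H15NO3	161.1052
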