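pathway	gene	accession	amplicon_bp	fwd_primer	rev_primer
Canonical	NFKB1A	NM_020529	116	CCGCAGGAGGTGCCG	ATCACTTCCATGGTCAGTGCC
Canonical	CXCL2/GroB	NM_002089	100	ATTCACCTCAAGAACATCCAAAGTG	GCCCATTCTTGAGTGTGGCTAT
Canonical	TNFA1P3/A20	NM_001270508	111	GAAGCACCATGTTTGAAGGATACTG	CTCTGCGCTGGCTCGATC
Canonical	IL-6	NM_000600	90	CTGGATTCAATGAGGAGACTTGC	TCAAATCTGTTCTGGAGGTACTCTAGG
Canonical	IL-8	NM_000584	92	AAGACATACTCCAAACCTTTCCACC	CAATAATTTCTGTGTTGGCGCA
Canonical	TSLP	NM_033035	91	TCTTGTAGCAATCGGCCACA	ACATTTCTTTGGCGAGCGA
Canonical	TRAF1	NM_005658	91	TGGAAGATCACCAATGTCACCA	ATACTTGGCAGTGTAGAAGGCTGG
Canonical	TRAF3	NM_145752	91	GAAGGCGTGTAAATACCGGG	ACAGTCGGTGTCTTCGTGTTTCT
Canonical	NFKB2	NM_001077494	96	ACATGACTGCCCAATTTAACAACC	GGAGCCGCTGCCTCTGA
Canonical	IL-25	NM_022789	91	CACCCAGAGTCCTGTAGGGC	GGTTCAAGTCTCTGTCCAACTCATATC
Canonical	IL-33	NM_033439	51	AACACCCCTCAAATGAATCAGGT	TTGGCATGCAACCAGAAGTCT
Noncanonical EMT	TNIP1	NM_001252385	92	ATCCAGTGGCACCTCCTCTG	CCAGCGCCATCGCATT
Noncanonical EMT	SMA/ACTA2	NM_001141945	91	TGTAAGGCCGGCTTTGCT	TTCCCACCATCACCCCCT
Noncanonical EMT	Col1A1	NM_000088	95	CCAGAAGAACTGGTACATCAGCA	CGCCATACTCGAACTGGAATC
Noncanonical EMT	Vimentin	NM_003380	91	GCTCAATGTTAAGATGGCCCTT	TGGAAGAGGCAGAGAAATCCTG
Noncanonical EMT	Desmin	NM_001927	91	GGAGAGGAGAGCCGGATCA	GGACCTCAGAACCCCTTTGC
Noncanonical EMT	Twist1	NM_000474	101	TCTCGGTCTGGAGGATGGA	CAATGACATCTAGGTCTCCG
Noncanonical EMT	Twist2	NM_001271893	119	ACGAGCGCCTCAGCTACG	CGCGACGGACAGCCCTG
Noncanonical EMT	SLUG	AF084243	91	TGTGTGGACTACCGCTGCTC	ACTCACTCGCCCCAAAGATG
Noncanonical EMT	SNAI1	NM_005985	95	GCGCTCTTTCCTCGTCAGG	GGGCTGCTGGAAGGTAAACTCT
Noncanonical EMT	ITGA2	NM_002203	91	AGCCGAAGTACCAACAGGAGTTATA	GCCGAGCTTCCATAAAATTGC
Noncanonical EMT	FSP1/S100A4	NM_002961	91	AGGGTGACAAGTTCAAGCTCAAC	GCTTCATCTGTCCTTTTCCCC
IFN	IFNb	NM_002176	95	GCAGTTCCAGAAGGAGGACG	TCCAGCCAGTGCTAGATGAATC
IFN	IFNa6	NM_021002	91	GTGGTGCTCAGCTGCAAGTC	CCAGGAGCATCATGGTCCTC
IFN	IFNa21	NM_002175	91	TGATCTGCCTCAGACCCACA	CTTCAGGCAGGAGAAAGGAGAG
IFN	CCL5/RANTES	NM_002985	96	TCTACACCAGTGGCAAGTGCTC	CCCGAACCCATTTCTTCTCTG
IFN	DDX58/RIG1	NM_014314	132	CCACTTAAACCCAGAGACAATAACAA	TTGCCACGTCCAGTCAATATG
IFN	LMP2	NM_002800	91	TTCACCACAGACGCTATTGCTC	CCACACCGGCAGCTGTAAT
IFN	TAP1	NM_000593	91	GTTTTTCCAACAGAACCAGACAGG	GCTCAGATTCTCACTCAGAGAATCACT
IFN	STAT1	NM_007315	104	TCCTGCTGCGGTTCAGTG	GGGTTCAACCGCATGGAAG
IFN	STAT2	NM_005419	118	CCTGAAACACAGGCTCATTGTG	TGGCACCAGCCCTAGTTCC
IFN	IRF1	NM_002198	91	AGCAAGGCCAAGAGGAAGTCA	TGCTGTGGTCATCAGGCAGA
IFN	IRF9	NM_006084	91	AGCCACAGGAAGTTACAGACACAA	GCAGTGAGTAGTCTGGCTCTGGA
IFN	SOCS3	NM_003955	91	CTTTCTGATCCGCGACAGCT	ACACTGGATGCGCAGGTTC
IFN	IF127	NM_001130080	91	CAGTCACTGGGAGCAACTGGA	GCCCAGGATGAACTTGGTCA
IFN	MX1	NM_001144925	106	GAACCACCCATATTTCAGGGATC	ATGTGTGATGAGCTCGCTGGTA
IFN	IFNL1	NM_172140	103	AAGCCCACCACAACTGGG	ACTCTTCCAAGGCGTCCC
IFN	IFNL2	NM_172138	101	ACATGACTGGGGACTGCAC	ATCCGGGAGAGCCCCGT
IFN	IFNL3	NM_172139	99	ATGACCGGGGACTGCATG	ATCCGGGAGAGCCCCGC
Growth factor	Fos	NM_005252	91	GGGCAAGGTGGAACAGTTATCT	GTTGCGGCATTTGGCTG
Growth factor	c-Jun	NM_002228	91	GTCCCAGGAGCGGATCAAG	GGCGATTCTCTCCAGCTTCC
Growth factor	SOD2	NM_000636	90	TGCTTGTCCAAATCAGGATCC	TGAAGGTAGTAAGCGTGCTCCC
Growth factor	TM4SF1	NM_014220	91	GAGGTGGCCTGCTGATGCT	CCACAGTTTTCATGGCCACAG
ROS/DNA	NOX1	NM_007052	91	GGGCATCCCCCTGAGTCT	TCTGCTGGGAGCGGTAAAAC
ROS/DNA	NOX4	NM_016931	91	ACTCAACACCCTGTTGGATGACT	CCAACGGAAGGACTGGATATCT
ROS/DNA	HOXB9	NM_024017	91	GGCCGGATCAAACCAACC	TCCAGCGTCTGGTATTTGGTG
ROS/DNA	ATM	NM_000051	127	GCTTCTCAGGATAATCCGCAAG	CCAAGCAGCTTCCAACAGC
ROS/DNA	STK39	NM_013233	91	GCCCAAAGAGCCAAAAAGGT	CGTCGTCACTCCACTCCCA
Cell cycle	PCNA	NM_002592	91	TGCGCCGGCAATGAA	CTTTCTCCTGGTTTGGTGCTTC
Cell cycle	CDKN1A	NM_000389	92	AGCAGGCTGAAGGGTCCC	GCGTTTGGAGTGGTAGAAATCTGT
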