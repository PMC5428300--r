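# Widely used plant DNA-barcoding primers. rbcLa-F/rbcLa-R, matK-xf,
# matK-MALP, ITS1 and ITS4 sequences are printed in the study's methods
# literature; trnHf_05 (Tate & Simpson 2003) and psbA3_f (Sang et al. 1997)
# are externally sourced from the cited primer literature. All sequences
# are user-overridable by supplying a custom table of the same layout.
name	sequence	orientation	marker
rbcLa-F	ATGTCACCACAAACAGAGACTAAAGC	forward	rbcL
rbcLa-R	GTAAAATCAAGTCCACCRCG	reverse	rbcL
matK-xf	TAATTTACGATCAATTCATTC	forward	matK
matK-MALP	ACAAGAAAGTCGAAGTAT	reverse	matK
trnHf_05	CGCGCATGGTGGATTCACAATCC	forward	trnH-psbA
psbA3_f	GTTATGCATGAACGTAATGCTC	reverse	trnH-psbA
ITS1	TCCGTAGGTGAACCTGCGG	forward	ITS
ITS4	TCCTCCGCTTATTGATATGC	reverse	ITS
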