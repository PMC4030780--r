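proband_id	de_novo	compound_het	homozygous	hemizygous	cnv	cnv_mode
F1	.	HEPHL1;PRKDC;ZNF44	.	BCORL1;FAM47A;KCNE1L;MAGEA6;ZCCHC12	.	.
F2	GRIN2A	FAM83E;KIAA1239;KIAA1755;LAMA5;MIA3	.	.	.	.
F3	PPFIBP2	C16orf91;C9orf79;CCDC144NL;NHSL1	.	CCDC22;SHROOM2	H2BFM;H2BFWT	cnv_x_linked
F5	.	DLC1;TTN	.	FAM70A;FTHL17;GPR112;PCDH19;RBMXL3;WDR44	.	.
F6	C11orf41;NF1;SMARCC2;ZHX3	FAM188B;RELN;RERE	AXL	.	.	.
F7	UNC80;WFDC8	MUC16;TSC22D1;TTN	.	.	.	.
F8	CD244	LY75-CD302;TTN;WDR59	.	PLXNB3;RBBP7;SRPX2	.	.
F9	PARD3B	ABCA13;COL6A6;GNAS;KIAA1462;MUC17;SRRM2;TRPM8	.	ATP2B3;CCDC22	.	.
F10	ATP6V1B2;SEMA4D	C19orf28;CDHR1;DNAH10;MACF1	.	.	.	.
F11	.	REST	.	CITED1;MXRA5;NR0B1	.	.
F12	.	FRG1B;TTN;ZNF451	.	.	.	.
F13	.	FRAS1;SPTBN5;TPO	.	ALG13;DDX26B;MAP7D3;TLR7	.	.
F14	KCTD8;STX12	ADNP;ANO7;CENPF;TDRD6	.	.	GPM6B;OFD1	cnv_de_novo
F15	DOCK1	ABLIM3;VCAN	.	.	.	.
F16	PPFIBP2	C16orf91;C9orf79;CCDC144NL;NHSL1	.	SHROOM2	.	.
F17	.	ABCA3;AKAP11;DEPDC1;PAFAH2;POM121C	.	.	.	.
F18	ABCB9;FAM3D	PCCB;TTN;ZFHX3	.	CXorf57;DUSP21;F9;FOXR2;HS6ST2;NKAP;RBMX2	.	.
F19	DNAJC13;NLRP1;PARD3B	AHNAK2;C20orf90;CD163L1;DNAH1;DNAH5;DNAH6;FSTL4;PHLPP2	ADAD2;PCNT	COL4A6;GYG2;PNMA3;SATL1;SHROOM2	SSX3;SSX4;SSX4B	cnv_x_linked
F20	COL2A1	CHD7;EPB41L2;GPR98;VPS13D	.	FAM58A;MTCP1NB;PLXNA3;SLC10A3	.	.
F21	.	CACNA1H;PKHD1	KIF26A	ARMCX2;EDA2R;HTATSF1;MAP7D3;MTMR8;MXRA5	.	.
F22	TACR2	DECR1;DUOXA1;NEB;VPS13C	PCDHB7	MAP7D3	.	.
F23	FGFR3	C1orf129;SHANK2;TTN	GFM2	MAP3K15;MAP7D3	.	.
F25	PNLIPRP1;SMARCC1	HSPG2;IQGAP3	.	BCOR;RAB40A;USP26	.	.
F26	KDM5B;STAU2	GNRHR2	.	HTATSF1;MTMR1;PIR	.	.
F27	C2orf40;INSC	.	.	.	.	.
F28	PPP6R1	CYP24A1;KIAA1109;KIAA1609;SLC39A11	.	.	.	.
F29	.	ABCA13;MCF2L2;NLRP12;POM121C;TTN;ZNF831	TTN	.	.	.
F31	FMNL3	FAH	.	.	.	.
F32	.	.	.	.	.	.
F33	SEC31B;EGFL6	AGRN;NUDT19	.	.	.	.
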