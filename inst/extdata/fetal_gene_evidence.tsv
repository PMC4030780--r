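gene	known_human_disease_gene	disease_hpo	identical_variant_reported_pathogenic	damaging_variant_class_in_known_domain	dosage_sensitive_loss	model_organism_phenotype_overlap	functional_plausibility	expression_relevant
FGFR3	TRUE	HP:9010001;HP:9010002;HP:9010003;HP:9010004	TRUE	FALSE	FALSE	TRUE	TRUE	TRUE
COL2A1	TRUE	HP:9010005;HP:9020004;HP:9010004;HP:9050002	FALSE	TRUE	FALSE	TRUE	TRUE	TRUE
OFD1	TRUE	HP:9030002;HP:9050003;HP:9010007	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE
PRKDC	TRUE	HP:9150001;HP:9050001;HP:9010010;HP:9090001	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
DLC1	FALSE	.	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
NF1	TRUE	HP:9120001;HP:9020009	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
SMARCC2	FALSE	.	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE
RERE	FALSE	.	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
MACF1	FALSE	.	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
FRAS1	TRUE	HP:9010007;HP:9040001;HP:9090001;HP:9050004	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE
GRIN2A	TRUE	HP:9100001;HP:9100002	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
PARD3B	FALSE	.	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
SEMA4D	FALSE	.	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
CHD7	TRUE	HP:9100002;HP:9100001	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
PCDH19	TRUE	HP:9100001;HP:9100002	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
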