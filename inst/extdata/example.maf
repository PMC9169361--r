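#version 2.4
Hugo_Symbol	Tumor_Sample_Barcode	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification
TP53	TCGA-01	chr1	11	C	T	Missense_Mutation
ERCC2	TCGA-01	chr1	25	G	A	Missense_Mutation
ATM	TCGA-02	chr1	40	C	G	Silent
FGFR3	TCGA-02	chr1	55	TA	T	Frame_Shift_Del
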