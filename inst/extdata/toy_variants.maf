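Tumor_Sample_Barcode	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2
S1	chr1	11	T	A
S1	chr1	21	G	A
S1	chr1	31	A	C
S1	chr1	41	G	A
S1	chr1	51	A	C
S2	chr1	61	C	A
S2	chr1	71	C	A
S2	chr1	81	A	C
S2	chr1	91	C	A
S2	chr1	101	A	C
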