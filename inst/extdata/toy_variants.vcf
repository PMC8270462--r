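##fileformat=VCFv4.2
##contig=<ID=chr1,length=600>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr1	11	.	T	A	.	PASS	.	GT	0/1	0/0
chr1	21	.	G	A	.	PASS	.	GT	0/1	0/0
chr1	31	.	A	C	.	PASS	.	GT	0/1	0/0
chr1	41	.	G	A	.	PASS	.	GT	0/1	0/0
chr1	51	.	A	C	.	PASS	.	GT	0/1	0/0
chr1	61	.	C	A	.	PASS	.	GT	0/0	0/1
chr1	71	.	C	A	.	PASS	.	GT	0/0	0/1
chr1	81	.	A	C	.	PASS	.	GT	0/0	0/1
chr1	91	.	C	A	.	PASS	.	GT	0/0	0/1
chr1	101	.	A	C	.	PASS	.	GT	0/0	0/1
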