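##fileformat=VCFv4.2
##source=synthetic example for the four-SNP oxytocin-pathway panel
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
3	8762685	rs1042778	G	T	.	PASS	.	GT	0/0	0/1	1/1
3	8777228	rs2254298	G	A	.	PASS	.	GT	0/0	0/1	./.
3	8804371	rs53576	A	G	.	PASS	.	GT	0/1	1/1	0/0
4	15703494	rs3796863	C	A	.	PASS	.	GT	0/0	1/0	1/1
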