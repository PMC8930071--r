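##fileformat=VCFv4.2
##source=episcreen synthetic toy fixture (hand-written, not from any cohort)
##contig=<ID=6>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I1	I2	I3	I4	I5	I6
6	160900000	rsA	T	C	.	PASS	.	GT:DS	0/0:0.02	0/1:0.98	1/1:1.97	0/1:1.10	0/0:0.00	0/1:0.95
6	160920000	rsB	G	A	.	PASS	.	GT:DS	0/1:1.01	0/0:0.10	0/1:0.90	1/1:2.00	0/0:0.05	./.:.
6	160950000	rsC	A	G	.	PASS	.	GT:DS	1/1:2.00	1/0:1.00	1/1:1.90	1/1:2.00	1/1:2.00	1/1:1.98
6	160980000	rsD	C	T	.	PASS	.	GT:DS	0/0:0.00	0/0:0.01	0/0:0.00	0/1:1.00	0/0:0.02	0/0:0.00
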