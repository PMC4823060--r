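##fileformat=VCFv4.2
##source=somaticsieve-0.1.0
##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">
##INFO=<ID=VAF,Number=1,Type=Float,Description="Tumor variant allele fraction">
##INFO=<ID=VQ,Number=1,Type=Float,Description="Phred-like variant quality">
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mean mapping quality of alt reads">
##INFO=<ID=RMF,Number=1,Type=Float,Description="Remappability ambiguous-read fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	1700	rs000001	G	A	.	.	.
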