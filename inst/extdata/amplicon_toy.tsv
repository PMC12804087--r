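sample	chrom	pos	ref	alt	caller_pass	vaf	n_amplicons	mutant_reads
A1	chr3	100	C	T	TRUE	0.005	3	20
A2	chr3	200	C	A	TRUE	0.01	2	5
A3	chr3	300	T	C	TRUE	0.5	4	100
A4	chr3	400	G	A	TRUE	0.2	2	40
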