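sample	chrom	pos	ref	alt	mouse	caller_pass	mgp_overlap	germline_overlap	alt_reads	alt_reads_baq30	normals_gapped	mappability	normals_somatic	max_tumour_vaf	normal_vaf	vaf
T1	chr1	100	C	T	M1	TRUE	FALSE	FALSE	10	8	0	1	0	0.3	0	0.3
T2	chr1	200	C	T	M1	TRUE	FALSE	FALSE	1	1	0	1	0	0.2	0	0.2
T3	chr1	300	G	A	M1	TRUE	FALSE	FALSE	10	10	4	1	0	0.2	0	0.2
T4	chr1	400	A	G	M1	TRUE	FALSE	FALSE	10	10	0	0.8	0	0.2	0	0.2
T5	chr1	500	T	C	M1	TRUE	FALSE	FALSE	10	10	0	1	2	0.2	0	0.2
T6	chr1	100	C	T	M2	TRUE	FALSE	FALSE	10	10	0	1	0	0.3	0.02	0.1
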