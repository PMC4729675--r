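# Published benchmark statistics (biased docking on the two RRM test
# complexes): per fragment, the RMSD of the best-fitting library conformer
# to the bound fragment and the minimum RMSD among the top-20% docked
# poses. Angstrom, coarse-grained representation.
complex	fragment	bestfit_rmsd	min_docked_rmsd
1B7F	frag1	0.6	2.3
1B7F	frag2	1.0	1.5
1B7F	frag3	0.8	1.1
1B7F	frag4	1.1	1.2
1B7F	frag5	0.4	1.4
1B7F	frag6	1.8	2.0
1CVJ	frag1	0.3	0.8
1CVJ	frag2	0.3	0.7
1CVJ	frag3	1.0	1.3
1CVJ	frag4	0.4	0.9
1CVJ	frag5	0.3	1.1
1CVJ	frag6	1.8	2.9
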