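# Published bound-docking hit counts per fragment: hits (pose RMSD < 2 A)
# in the top-20% docking pool and hits kept by the single-pool
# chain-propensity filter.
complex	fragment	hits_top20	hits_filtered
1B7F	frag1	11	10
1B7F	frag2	13	13
1B7F	frag3	29	25
1B7F	frag4	31	25
1B7F	frag5	32	31
1B7F	frag6	20	20
1CVJ	frag1	9	9
1CVJ	frag2	21	21
1CVJ	frag3	17	16
1CVJ	frag4	13	13
1CVJ	frag5	3	3
1CVJ	frag6	5	5
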