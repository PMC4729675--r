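# Toy coarse-grained pair table for the synthetic benchmark.
# Fragment bead types 1-18 (six bead slots per nucleotide, cycling with
# period 3 nucleotides so that no two nearby nucleotides share types);
# receptor groove partner types 21-38 attract only the matching fragment
# type, other combinations are repulsive; type 40 is the repulsive
# receptor core. The matched-pair minimum sits at r* = R*sqrt(4/3) = 4 A
# with depth 27*eps/256.
type_i	type_j	epsilon	R	attractive
1	21	5	3.4641016	1
1	22	0.2	3	0
1	23	0.2	3	0
1	24	0.2	3	0
1	25	0.2	3	0
1	26	0.2	3	0
1	27	0.2	3	0
1	28	0.2	3	0
1	29	0.2	3	0
1	30	0.2	3	0
1	31	0.2	3	0
1	32	0.2	3	0
1	33	0.2	3	0
1	34	0.2	3	0
1	35	0.2	3	0
1	36	0.2	3	0
1	37	0.2	3	0
1	38	0.2	3	0
1	40	1	3	0
2	21	0.2	3	0
2	22	5	3.4641016	1
2	23	0.2	3	0
2	24	0.2	3	0
2	25	0.2	3	0
2	26	0.2	3	0
2	27	0.2	3	0
2	28	0.2	3	0
2	29	0.2	3	0
2	30	0.2	3	0
2	31	0.2	3	0
2	32	0.2	3	0
2	33	0.2	3	0
2	34	0.2	3	0
2	35	0.2	3	0
2	36	0.2	3	0
2	37	0.2	3	0
2	38	0.2	3	0
2	40	1	3	0
3	21	0.2	3	0
3	22	0.2	3	0
3	23	5	3.4641016	1
3	24	0.2	3	0
3	25	0.2	3	0
3	26	0.2	3	0
3	27	0.2	3	0
3	28	0.2	3	0
3	29	0.2	3	0
3	30	0.2	3	0
3	31	0.2	3	0
3	32	0.2	3	0
3	33	0.2	3	0
3	34	0.2	3	0
3	35	0.2	3	0
3	36	0.2	3	0
3	37	0.2	3	0
3	38	0.2	3	0
3	40	1	3	0
4	21	0.2	3	0
4	22	0.2	3	0
4	23	0.2	3	0
4	24	5	3.4641016	1
4	25	0.2	3	0
4	26	0.2	3	0
4	27	0.2	3	0
4	28	0.2	3	0
4	29	0.2	3	0
4	30	0.2	3	0
4	31	0.2	3	0
4	32	0.2	3	0
4	33	0.2	3	0
4	34	0.2	3	0
4	35	0.2	3	0
4	36	0.2	3	0
4	37	0.2	3	0
4	38	0.2	3	0
4	40	1	3	0
5	21	0.2	3	0
5	22	0.2	3	0
5	23	0.2	3	0
5	24	0.2	3	0
5	25	5	3.4641016	1
5	26	0.2	3	0
5	27	0.2	3	0
5	28	0.2	3	0
5	29	0.2	3	0
5	30	0.2	3	0
5	31	0.2	3	0
5	32	0.2	3	0
5	33	0.2	3	0
5	34	0.2	3	0
5	35	0.2	3	0
5	36	0.2	3	0
5	37	0.2	3	0
5	38	0.2	3	0
5	40	1	3	0
6	21	0.2	3	0
6	22	0.2	3	0
6	23	0.2	3	0
6	24	0.2	3	0
6	25	0.2	3	0
6	26	5	3.4641016	1
6	27	0.2	3	0
6	28	0.2	3	0
6	29	0.2	3	0
6	30	0.2	3	0
6	31	0.2	3	0
6	32	0.2	3	0
6	33	0.2	3	0
6	34	0.2	3	0
6	35	0.2	3	0
6	36	0.2	3	0
6	37	0.2	3	0
6	38	0.2	3	0
6	40	1	3	0
7	21	0.2	3	0
7	22	0.2	3	0
7	23	0.2	3	0
7	24	0.2	3	0
7	25	0.2	3	0
7	26	0.2	3	0
7	27	5	3.4641016	1
7	28	0.2	3	0
7	29	0.2	3	0
7	30	0.2	3	0
7	31	0.2	3	0
7	32	0.2	3	0
7	33	0.2	3	0
7	34	0.2	3	0
7	35	0.2	3	0
7	36	0.2	3	0
7	37	0.2	3	0
7	38	0.2	3	0
7	40	1	3	0
8	21	0.2	3	0
8	22	0.2	3	0
8	23	0.2	3	0
8	24	0.2	3	0
8	25	0.2	3	0
8	26	0.2	3	0
8	27	0.2	3	0
8	28	5	3.4641016	1
8	29	0.2	3	0
8	30	0.2	3	0
8	31	0.2	3	0
8	32	0.2	3	0
8	33	0.2	3	0
8	34	0.2	3	0
8	35	0.2	3	0
8	36	0.2	3	0
8	37	0.2	3	0
8	38	0.2	3	0
8	40	1	3	0
9	21	0.2	3	0
9	22	0.2	3	0
9	23	0.2	3	0
9	24	0.2	3	0
9	25	0.2	3	0
9	26	0.2	3	0
9	27	0.2	3	0
9	28	0.2	3	0
9	29	5	3.4641016	1
9	30	0.2	3	0
9	31	0.2	3	0
9	32	0.2	3	0
9	33	0.2	3	0
9	34	0.2	3	0
9	35	0.2	3	0
9	36	0.2	3	0
9	37	0.2	3	0
9	38	0.2	3	0
9	40	1	3	0
10	21	0.2	3	0
10	22	0.2	3	0
10	23	0.2	3	0
10	24	0.2	3	0
10	25	0.2	3	0
10	26	0.2	3	0
10	27	0.2	3	0
10	28	0.2	3	0
10	29	0.2	3	0
10	30	5	3.4641016	1
10	31	0.2	3	0
10	32	0.2	3	0
10	33	0.2	3	0
10	34	0.2	3	0
10	35	0.2	3	0
10	36	0.2	3	0
10	37	0.2	3	0
10	38	0.2	3	0
10	40	1	3	0
11	21	0.2	3	0
11	22	0.2	3	0
11	23	0.2	3	0
11	24	0.2	3	0
11	25	0.2	3	0
11	26	0.2	3	0
11	27	0.2	3	0
11	28	0.2	3	0
11	29	0.2	3	0
11	30	0.2	3	0
11	31	5	3.4641016	1
11	32	0.2	3	0
11	33	0.2	3	0
11	34	0.2	3	0
11	35	0.2	3	0
11	36	0.2	3	0
11	37	0.2	3	0
11	38	0.2	3	0
11	40	1	3	0
12	21	0.2	3	0
12	22	0.2	3	0
12	23	0.2	3	0
12	24	0.2	3	0
12	25	0.2	3	0
12	26	0.2	3	0
12	27	0.2	3	0
12	28	0.2	3	0
12	29	0.2	3	0
12	30	0.2	3	0
12	31	0.2	3	0
12	32	5	3.4641016	1
12	33	0.2	3	0
12	34	0.2	3	0
12	35	0.2	3	0
12	36	0.2	3	0
12	37	0.2	3	0
12	38	0.2	3	0
12	40	1	3	0
13	21	0.2	3	0
13	22	0.2	3	0
13	23	0.2	3	0
13	24	0.2	3	0
13	25	0.2	3	0
13	26	0.2	3	0
13	27	0.2	3	0
13	28	0.2	3	0
13	29	0.2	3	0
13	30	0.2	3	0
13	31	0.2	3	0
13	32	0.2	3	0
13	33	5	3.4641016	1
13	34	0.2	3	0
13	35	0.2	3	0
13	36	0.2	3	0
13	37	0.2	3	0
13	38	0.2	3	0
13	40	1	3	0
14	21	0.2	3	0
14	22	0.2	3	0
14	23	0.2	3	0
14	24	0.2	3	0
14	25	0.2	3	0
14	26	0.2	3	0
14	27	0.2	3	0
14	28	0.2	3	0
14	29	0.2	3	0
14	30	0.2	3	0
14	31	0.2	3	0
14	32	0.2	3	0
14	33	0.2	3	0
14	34	5	3.4641016	1
14	35	0.2	3	0
14	36	0.2	3	0
14	37	0.2	3	0
14	38	0.2	3	0
14	40	1	3	0
15	21	0.2	3	0
15	22	0.2	3	0
15	23	0.2	3	0
15	24	0.2	3	0
15	25	0.2	3	0
15	26	0.2	3	0
15	27	0.2	3	0
15	28	0.2	3	0
15	29	0.2	3	0
15	30	0.2	3	0
15	31	0.2	3	0
15	32	0.2	3	0
15	33	0.2	3	0
15	34	0.2	3	0
15	35	5	3.4641016	1
15	36	0.2	3	0
15	37	0.2	3	0
15	38	0.2	3	0
15	40	1	3	0
16	21	0.2	3	0
16	22	0.2	3	0
16	23	0.2	3	0
16	24	0.2	3	0
16	25	0.2	3	0
16	26	0.2	3	0
16	27	0.2	3	0
16	28	0.2	3	0
16	29	0.2	3	0
16	30	0.2	3	0
16	31	0.2	3	0
16	32	0.2	3	0
16	33	0.2	3	0
16	34	0.2	3	0
16	35	0.2	3	0
16	36	5	3.4641016	1
16	37	0.2	3	0
16	38	0.2	3	0
16	40	1	3	0
17	21	0.2	3	0
17	22	0.2	3	0
17	23	0.2	3	0
17	24	0.2	3	0
17	25	0.2	3	0
17	26	0.2	3	0
17	27	0.2	3	0
17	28	0.2	3	0
17	29	0.2	3	0
17	30	0.2	3	0
17	31	0.2	3	0
17	32	0.2	3	0
17	33	0.2	3	0
17	34	0.2	3	0
17	35	0.2	3	0
17	36	0.2	3	0
17	37	5	3.4641016	1
17	38	0.2	3	0
17	40	1	3	0
18	21	0.2	3	0
18	22	0.2	3	0
18	23	0.2	3	0
18	24	0.2	3	0
18	25	0.2	3	0
18	26	0.2	3	0
18	27	0.2	3	0
18	28	0.2	3	0
18	29	0.2	3	0
18	30	0.2	3	0
18	31	0.2	3	0
18	32	0.2	3	0
18	33	0.2	3	0
18	34	0.2	3	0
18	35	0.2	3	0
18	36	0.2	3	0
18	37	0.2	3	0
18	38	5	3.4641016	1
18	40	1	3	0
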