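# SYNTHETIC default CFD mismatch penalties (not experimentally derived).
# penalty(position, guide_base, off_base); position 1 = PAM-distal.
# Drop in a published table with the same columns to reproduce
# experimental CFD values.
position	guide_base	off_base	penalty
1	A	A	1
1	A	C	0.7
1	A	G	0.98
1	A	T	0.7
1	C	A	0.7
1	C	C	1
1	C	G	0.7
1	C	T	0.98
1	G	A	0.98
1	G	C	0.7
1	G	G	1
1	G	T	0.7
1	T	A	0.7
1	T	C	0.98
1	T	G	0.7
1	T	T	1
2	A	A	1
2	A	C	0.669
2	A	G	0.955
2	A	T	0.669
2	C	A	0.669
2	C	C	1
2	C	G	0.669
2	C	T	0.955
2	G	A	0.955
2	G	C	0.669
2	G	G	1
2	G	T	0.669
2	T	A	0.669
2	T	C	0.955
2	T	G	0.669
2	T	T	1
3	A	A	1
3	A	C	0.637
3	A	G	0.911
3	A	T	0.637
3	C	A	0.637
3	C	C	1
3	C	G	0.637
3	C	T	0.911
3	G	A	0.911
3	G	C	0.637
3	G	G	1
3	G	T	0.637
3	T	A	0.637
3	T	C	0.911
3	T	G	0.637
3	T	T	1
4	A	A	1
4	A	C	0.606
4	A	G	0.866
4	A	T	0.606
4	C	A	0.606
4	C	C	1
4	C	G	0.606
4	C	T	0.866
4	G	A	0.866
4	G	C	0.606
4	G	G	1
4	G	T	0.606
4	T	A	0.606
4	T	C	0.866
4	T	G	0.606
4	T	T	1
5	A	A	1
5	A	C	0.575
5	A	G	0.821
5	A	T	0.575
5	C	A	0.575
5	C	C	1
5	C	G	0.575
5	C	T	0.821
5	G	A	0.821
5	G	C	0.575
5	G	G	1
5	G	T	0.575
5	T	A	0.575
5	T	C	0.821
5	T	G	0.575
5	T	T	1
6	A	A	1
6	A	C	0.543
6	A	G	0.776
6	A	T	0.543
6	C	A	0.543
6	C	C	1
6	C	G	0.543
6	C	T	0.776
6	G	A	0.776
6	G	C	0.543
6	G	G	1
6	G	T	0.543
6	T	A	0.543
6	T	C	0.776
6	T	G	0.543
6	T	T	1
7	A	A	1
7	A	C	0.512
7	A	G	0.732
7	A	T	0.512
7	C	A	0.512
7	C	C	1
7	C	G	0.512
7	C	T	0.732
7	G	A	0.732
7	G	C	0.512
7	G	G	1
7	G	T	0.512
7	T	A	0.512
7	T	C	0.732
7	T	G	0.512
7	T	T	1
8	A	A	1
8	A	C	0.481
8	A	G	0.687
8	A	T	0.481
8	C	A	0.481
8	C	C	1
8	C	G	0.481
8	C	T	0.687
8	G	A	0.687
8	G	C	0.481
8	G	G	1
8	G	T	0.481
8	T	A	0.481
8	T	C	0.687
8	T	G	0.481
8	T	T	1
9	A	A	1
9	A	C	0.449
9	A	G	0.642
9	A	T	0.449
9	C	A	0.449
9	C	C	1
9	C	G	0.449
9	C	T	0.642
9	G	A	0.642
9	G	C	0.449
9	G	G	1
9	G	T	0.449
9	T	A	0.449
9	T	C	0.642
9	T	G	0.449
9	T	T	1
10	A	A	1
10	A	C	0.418
10	A	G	0.597
10	A	T	0.418
10	C	A	0.418
10	C	C	1
10	C	G	0.418
10	C	T	0.597
10	G	A	0.597
10	G	C	0.418
10	G	G	1
10	G	T	0.418
10	T	A	0.418
10	T	C	0.597
10	T	G	0.418
10	T	T	1
11	A	A	1
11	A	C	0.387
11	A	G	0.553
11	A	T	0.387
11	C	A	0.387
11	C	C	1
11	C	G	0.387
11	C	T	0.553
11	G	A	0.553
11	G	C	0.387
11	G	G	1
11	G	T	0.387
11	T	A	0.387
11	T	C	0.553
11	T	G	0.387
11	T	T	1
12	A	A	1
12	A	C	0.356
12	A	G	0.508
12	A	T	0.356
12	C	A	0.356
12	C	C	1
12	C	G	0.356
12	C	T	0.508
12	G	A	0.508
12	G	C	0.356
12	G	G	1
12	G	T	0.356
12	T	A	0.356
12	T	C	0.508
12	T	G	0.356
12	T	T	1
13	A	A	1
13	A	C	0.324
13	A	G	0.463
13	A	T	0.324
13	C	A	0.324
13	C	C	1
13	C	G	0.324
13	C	T	0.463
13	G	A	0.463
13	G	C	0.324
13	G	G	1
13	G	T	0.324
13	T	A	0.324
13	T	C	0.463
13	T	G	0.324
13	T	T	1
14	A	A	1
14	A	C	0.293
14	A	G	0.418
14	A	T	0.293
14	C	A	0.293
14	C	C	1
14	C	G	0.293
14	C	T	0.418
14	G	A	0.418
14	G	C	0.293
14	G	G	1
14	G	T	0.293
14	T	A	0.293
14	T	C	0.418
14	T	G	0.293
14	T	T	1
15	A	A	1
15	A	C	0.262
15	A	G	0.374
15	A	T	0.262
15	C	A	0.262
15	C	C	1
15	C	G	0.262
15	C	T	0.374
15	G	A	0.374
15	G	C	0.262
15	G	G	1
15	G	T	0.262
15	T	A	0.262
15	T	C	0.374
15	T	G	0.262
15	T	T	1
16	A	A	1
16	A	C	0.23
16	A	G	0.329
16	A	T	0.23
16	C	A	0.23
16	C	C	1
16	C	G	0.23
16	C	T	0.329
16	G	A	0.329
16	G	C	0.23
16	G	G	1
16	G	T	0.23
16	T	A	0.23
16	T	C	0.329
16	T	G	0.23
16	T	T	1
17	A	A	1
17	A	C	0.199
17	A	G	0.284
17	A	T	0.199
17	C	A	0.199
17	C	C	1
17	C	G	0.199
17	C	T	0.284
17	G	A	0.284
17	G	C	0.199
17	G	G	1
17	G	T	0.199
17	T	A	0.199
17	T	C	0.284
17	T	G	0.199
17	T	T	1
18	A	A	1
18	A	C	0.168
18	A	G	0.239
18	A	T	0.168
18	C	A	0.168
18	C	C	1
18	C	G	0.168
18	C	T	0.239
18	G	A	0.239
18	G	C	0.168
18	G	G	1
18	G	T	0.168
18	T	A	0.168
18	T	C	0.239
18	T	G	0.168
18	T	T	1
19	A	A	1
19	A	C	0.136
19	A	G	0.195
19	A	T	0.136
19	C	A	0.136
19	C	C	1
19	C	G	0.136
19	C	T	0.195
19	G	A	0.195
19	G	C	0.136
19	G	G	1
19	G	T	0.136
19	T	A	0.136
19	T	C	0.195
19	T	G	0.136
19	T	T	1
20	A	A	1
20	A	C	0.105
20	A	G	0.15
20	A	T	0.105
20	C	A	0.105
20	C	C	1
20	C	G	0.105
20	C	T	0.15
20	G	A	0.15
20	G	C	0.105
20	G	G	1
20	G	T	0.105
20	T	A	0.105
20	T	C	0.15
20	T	G	0.105
20	T	T	1
21	A	A	1
21	A	C	0.105
21	A	G	0.15
21	A	T	0.105
21	C	A	0.105
21	C	C	1
21	C	G	0.105
21	C	T	0.15
21	G	A	0.15
21	G	C	0.105
21	G	G	1
21	G	T	0.105
21	T	A	0.105
21	T	C	0.15
21	T	G	0.105
21	T	T	1
22	A	A	1
22	A	C	0.105
22	A	G	0.15
22	A	T	0.105
22	C	A	0.105
22	C	C	1
22	C	G	0.105
22	C	T	0.15
22	G	A	0.15
22	G	C	0.105
22	G	G	1
22	G	T	0.105
22	T	A	0.105
22	T	C	0.15
22	T	G	0.105
22	T	T	1
23	A	A	1
23	A	C	0.105
23	A	G	0.15
23	A	T	0.105
23	C	A	0.105
23	C	C	1
23	C	G	0.105
23	C	T	0.15
23	G	A	0.15
23	G	C	0.105
23	G	G	1
23	G	T	0.105
23	T	A	0.105
23	T	C	0.15
23	T	G	0.105
23	T	T	1
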