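# SYNTHETIC CFD-style mismatch activity fractions (NOT the published empirical table).
# Stand-in with the real schema: penalty for a mismatch at protospacer position
# (1 = PAM-distal), guide_base = designed spacer base, site_base = genomic base on
# the protospacer strand. Values decline linearly toward the PAM with a flat
# transversion penalty; swap in an empirically derived table via load_cfd_tables().
position	guide_base	site_base	penalty
1	A	C	0.65
1	A	G	1
1	A	T	0.65
1	C	A	0.65
1	C	G	0.65
1	C	T	1
1	G	A	1
1	G	C	0.65
1	G	T	0.65
1	T	A	0.65
1	T	C	1
1	T	G	0.65
2	A	C	0.6209
2	A	G	0.9553
2	A	T	0.6209
2	C	A	0.6209
2	C	G	0.6209
2	C	T	0.9553
2	G	A	0.9553
2	G	C	0.6209
2	G	T	0.6209
2	T	A	0.6209
2	T	C	0.9553
2	T	G	0.6209
3	A	C	0.5918
3	A	G	0.9105
3	A	T	0.5918
3	C	A	0.5918
3	C	G	0.5918
3	C	T	0.9105
3	G	A	0.9105
3	G	C	0.5918
3	G	T	0.5918
3	T	A	0.5918
3	T	C	0.9105
3	T	G	0.5918
4	A	C	0.5628
4	A	G	0.8658
4	A	T	0.5628
4	C	A	0.5628
4	C	G	0.5628
4	C	T	0.8658
4	G	A	0.8658
4	G	C	0.5628
4	G	T	0.5628
4	T	A	0.5628
4	T	C	0.8658
4	T	G	0.5628
5	A	C	0.5337
5	A	G	0.8211
5	A	T	0.5337
5	C	A	0.5337
5	C	G	0.5337
5	C	T	0.8211
5	G	A	0.8211
5	G	C	0.5337
5	G	T	0.5337
5	T	A	0.5337
5	T	C	0.8211
5	T	G	0.5337
6	A	C	0.5046
6	A	G	0.7763
6	A	T	0.5046
6	C	A	0.5046
6	C	G	0.5046
6	C	T	0.7763
6	G	A	0.7763
6	G	C	0.5046
6	G	T	0.5046
6	T	A	0.5046
6	T	C	0.7763
6	T	G	0.5046
7	A	C	0.4755
7	A	G	0.7316
7	A	T	0.4755
7	C	A	0.4755
7	C	G	0.4755
7	C	T	0.7316
7	G	A	0.7316
7	G	C	0.4755
7	G	T	0.4755
7	T	A	0.4755
7	T	C	0.7316
7	T	G	0.4755
8	A	C	0.4464
8	A	G	0.6868
8	A	T	0.4464
8	C	A	0.4464
8	C	G	0.4464
8	C	T	0.6868
8	G	A	0.6868
8	G	C	0.4464
8	G	T	0.4464
8	T	A	0.4464
8	T	C	0.6868
8	T	G	0.4464
9	A	C	0.4174
9	A	G	0.6421
9	A	T	0.4174
9	C	A	0.4174
9	C	G	0.4174
9	C	T	0.6421
9	G	A	0.6421
9	G	C	0.4174
9	G	T	0.4174
9	T	A	0.4174
9	T	C	0.6421
9	T	G	0.4174
10	A	C	0.3883
10	A	G	0.5974
10	A	T	0.3883
10	C	A	0.3883
10	C	G	0.3883
10	C	T	0.5974
10	G	A	0.5974
10	G	C	0.3883
10	G	T	0.3883
10	T	A	0.3883
10	T	C	0.5974
10	T	G	0.3883
11	A	C	0.3592
11	A	G	0.5526
11	A	T	0.3592
11	C	A	0.3592
11	C	G	0.3592
11	C	T	0.5526
11	G	A	0.5526
11	G	C	0.3592
11	G	T	0.3592
11	T	A	0.3592
11	T	C	0.5526
11	T	G	0.3592
12	A	C	0.3301
12	A	G	0.5079
12	A	T	0.3301
12	C	A	0.3301
12	C	G	0.3301
12	C	T	0.5079
12	G	A	0.5079
12	G	C	0.3301
12	G	T	0.3301
12	T	A	0.3301
12	T	C	0.5079
12	T	G	0.3301
13	A	C	0.3011
13	A	G	0.4632
13	A	T	0.3011
13	C	A	0.3011
13	C	G	0.3011
13	C	T	0.4632
13	G	A	0.4632
13	G	C	0.3011
13	G	T	0.3011
13	T	A	0.3011
13	T	C	0.4632
13	T	G	0.3011
14	A	C	0.272
14	A	G	0.4184
14	A	T	0.272
14	C	A	0.272
14	C	G	0.272
14	C	T	0.4184
14	G	A	0.4184
14	G	C	0.272
14	G	T	0.272
14	T	A	0.272
14	T	C	0.4184
14	T	G	0.272
15	A	C	0.2429
15	A	G	0.3737
15	A	T	0.2429
15	C	A	0.2429
15	C	G	0.2429
15	C	T	0.3737
15	G	A	0.3737
15	G	C	0.2429
15	G	T	0.2429
15	T	A	0.2429
15	T	C	0.3737
15	T	G	0.2429
16	A	C	0.2138
16	A	G	0.3289
16	A	T	0.2138
16	C	A	0.2138
16	C	G	0.2138
16	C	T	0.3289
16	G	A	0.3289
16	G	C	0.2138
16	G	T	0.2138
16	T	A	0.2138
16	T	C	0.3289
16	T	G	0.2138
17	A	C	0.1847
17	A	G	0.2842
17	A	T	0.1847
17	C	A	0.1847
17	C	G	0.1847
17	C	T	0.2842
17	G	A	0.2842
17	G	C	0.1847
17	G	T	0.1847
17	T	A	0.1847
17	T	C	0.2842
17	T	G	0.1847
18	A	C	0.1557
18	A	G	0.2395
18	A	T	0.1557
18	C	A	0.1557
18	C	G	0.1557
18	C	T	0.2395
18	G	A	0.2395
18	G	C	0.1557
18	G	T	0.1557
18	T	A	0.1557
18	T	C	0.2395
18	T	G	0.1557
19	A	C	0.1266
19	A	G	0.1947
19	A	T	0.1266
19	C	A	0.1266
19	C	G	0.1266
19	C	T	0.1947
19	G	A	0.1947
19	G	C	0.1266
19	G	T	0.1266
19	T	A	0.1266
19	T	C	0.1947
19	T	G	0.1266
20	A	C	0.0975
20	A	G	0.15
20	A	T	0.0975
20	C	A	0.0975
20	C	G	0.0975
20	C	T	0.15
20	G	A	0.15
20	G	C	0.0975
20	G	T	0.0975
20	T	A	0.0975
20	T	C	0.15
20	T	G	0.0975
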