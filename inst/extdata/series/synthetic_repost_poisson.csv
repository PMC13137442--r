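time,value
0.50000000,0.06053993
1.50000000,0.05221468
2.50000000,0.05067895
3.50000000,0.05286130
4.50000000,0.05366958
5.50000000,0.06159069
6.50000000,0.05908503
7.50000000,0.06102489
8.50000000,0.06846104
9.50000000,0.06983511
10.50000000,0.07581636
11.50000000,0.08236340
12.50000000,0.08931458
13.50000000,0.09327514
14.50000000,0.09828645
15.50000000,0.10394439
16.50000000,0.10879405
17.50000000,0.11412868
18.50000000,0.12681862
19.50000000,0.12867766
20.50000000,0.13498222
21.50000000,0.13716457
22.50000000,0.14233754
23.50000000,0.15656321
24.50000000,0.16020045
25.50000000,0.16472680
26.50000000,0.16100873
27.50000000,0.18040737
28.50000000,0.18283220
29.50000000,0.18962173
30.50000000,0.19932105
31.50000000,0.20740382
32.50000000,0.21281927
33.50000000,0.21783059
34.50000000,0.21783059
35.50000000,0.22550921
36.50000000,0.22777239
37.50000000,0.23512771
38.50000000,0.24806014
39.50000000,0.24143227
40.50000000,0.25517297
41.50000000,0.24919172
42.50000000,0.26026511
43.50000000,0.27440996
44.50000000,0.27101520
45.50000000,0.27465244
46.50000000,0.28216941
47.50000000,0.28734239
48.50000000,0.28855480
49.50000000,0.28645328
50.50000000,0.29954737
51.50000000,0.31005496
52.50000000,0.31045910
53.50000000,0.31013579
54.50000000,0.31652118
55.50000000,0.31053993
56.50000000,0.32468477
57.50000000,0.32719043
58.50000000,0.33171678
59.50000000,0.33802134
60.50000000,0.32807953
61.50000000,0.34836728
62.50000000,0.34699321
63.50000000,0.34788231
64.50000000,0.34949887
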