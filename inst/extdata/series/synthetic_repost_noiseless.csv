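time,value
0.50000000,0.05806333
1.50000000,0.05546569
2.50000000,0.05436949
3.50000000,0.05455233
4.50000000,0.05581729
5.50000000,0.05799419
6.50000000,0.06093766
7.50000000,0.06452390
8.50000000,0.06864728
9.50000000,0.07321715
10.50000000,0.07815533
11.50000000,0.08339412
12.50000000,0.08887479
13.50000000,0.09454654
14.50000000,0.10036564
15.50000000,0.10629478
16.50000000,0.11230247
17.50000000,0.11836244
18.50000000,0.12445314
19.50000000,0.13055713
20.50000000,0.13666054
21.50000000,0.14275253
22.50000000,0.14882478
23.50000000,0.15487104
24.50000000,0.16088666
25.50000000,0.16686824
26.50000000,0.17281330
27.50000000,0.17871999
28.50000000,0.18458686
29.50000000,0.19041267
30.50000000,0.19619624
31.50000000,0.20193632
32.50000000,0.20763154
33.50000000,0.21328030
34.50000000,0.21888078
35.50000000,0.22443090
36.50000000,0.22992830
37.50000000,0.23537042
38.50000000,0.24075443
39.50000000,0.24607734
40.50000000,0.25133598
41.50000000,0.25652708
42.50000000,0.26164727
43.50000000,0.26669316
44.50000000,0.27166135
45.50000000,0.27654850
46.50000000,0.28135132
47.50000000,0.28606668
48.50000000,0.29069155
49.50000000,0.29522311
50.50000000,0.29965872
51.50000000,0.30399597
52.50000000,0.30823269
53.50000000,0.31236693
54.50000000,0.31639704
55.50000000,0.32032160
56.50000000,0.32413948
57.50000000,0.32784981
58.50000000,0.33145198
59.50000000,0.33494565
60.50000000,0.33833073
61.50000000,0.34160735
62.50000000,0.34477592
63.50000000,0.34783703
64.50000000,0.35079149
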