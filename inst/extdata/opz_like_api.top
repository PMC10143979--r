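; dispermd topology
[defaults]
f14_lj 0.5
f14_coul 0.5
[atoms]
; index name element resname molid charge sigma epsilon mass donor acceptor
1 O1 O OPZ 1 -0.300000 0.300000 0.712000 15.999000 0 1
2 HO H OPZ 1 0.220000 0.100000 0.065000 1.008000 1 0
3 C1 C OPZ 1 0.110000 0.350000 0.276000 12.011000 0 0
4 H1A H OPZ 1 0.040000 0.250000 0.126000 1.008000 0 0
5 H1B H OPZ 1 0.040000 0.250000 0.126000 1.008000 0 0
6 C2 C OPZ 1 0.270000 0.375000 0.439000 12.011000 0 0
7 O2 O OPZ 1 -0.250000 0.296000 0.879000 15.999000 0 1
8 N N OPZ 1 -0.370000 0.325000 0.711000 14.007000 0 1
9 HN H OPZ 1 0.180000 0.100000 0.065000 1.008000 1 0
10 C3 C OPZ 1 -0.020000 0.350000 0.276000 12.011000 0 0
11 H31 H OPZ 1 0.040000 0.250000 0.126000 1.008000 0 0
12 H32 H OPZ 1 0.040000 0.250000 0.126000 1.008000 0 0
13 C4 C OPZ 1 -0.180000 0.350000 0.276000 12.011000 0 0
14 H41 H OPZ 1 0.060000 0.250000 0.126000 1.008000 0 0
15 H42 H OPZ 1 0.060000 0.250000 0.126000 1.008000 0 0
16 H43 H OPZ 1 0.060000 0.250000 0.126000 1.008000 0 0
[bonds]
1 2 0.096047 50000.00
1 3 0.141000 100000.00
3 4 0.106283 50000.00
3 5 0.106283 50000.00
3 6 0.152069 100000.00
6 7 0.122090 100000.00
6 8 0.140656 100000.00
8 9 0.101237 50000.00
8 10 0.147733 100000.00
10 11 0.106419 50000.00
10 12 0.106419 50000.00
10 13 0.151819 100000.00
13 14 0.104403 50000.00
13 15 0.111467 50000.00
13 16 0.110114 50000.00
[angles]
2 1 3 128.6598 300.00
1 3 4 109.7989 300.00
1 3 5 109.7989 300.00
1 3 6 136.3322 300.00
4 3 5 97.6513 300.00
4 3 6 98.3246 300.00
5 3 6 98.3246 300.00
3 6 7 160.4427 300.00
3 6 8 106.4863 300.00
7 6 8 93.0710 300.00
6 8 9 143.1188 300.00
6 8 10 126.1916 300.00
9 8 10 90.6896 300.00
8 10 11 98.7809 300.00
8 10 12 98.7809 300.00
8 10 13 151.7382 300.00
11 10 12 106.0179 300.00
11 10 13 98.1127 300.00
12 10 13 98.1127 300.00
10 13 14 111.0764 300.00
10 13 15 130.1867 300.00
10 13 16 136.4685 300.00
14 13 15 79.1030 300.00
14 13 16 80.4870 300.00
15 13 16 92.6851 300.00
[pairs14]
1 7
1 8
2 4
2 5
2 6
3 9
3 10
4 7
4 8
5 7
5 8
6 11
6 12
6 13
7 9
7 10
8 14
8 15
8 16
9 11
9 12
9 13
11 14
11 15
11 16
12 14
12 15
12 16
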