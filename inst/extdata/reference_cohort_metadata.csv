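subject_id,sex,age_years,phq9_score,group
1,F,24,23,depressed
2,F,23,21,depressed
3,F,24,23,depressed
4,F,23,23,depressed
5,M,25,24,depressed
6,F,23,22,depressed
7,M,20,23,depressed
8,F,21,25,depressed
9,F,23,26,depressed
10,M,21,21,depressed
11,M,20,23,depressed
12,F,20,22,depressed
13,F,22,23,depressed
14,M,24,22,depressed
15,F,21,23,depressed
16,F,19,23,depressed
17,F,20,21,depressed
18,F,18,22,depressed
19,F,20,20,depressed
20,M,24,5,control
21,F,22,5,control
22,M,21,4,control
23,M,21,2,control
24,M,25,0,control
25,M,24,3,control
26,M,20,3,control
27,M,22,4,control
28,M,20,5,control
29,M,19,4,control
30,M,21,5,control
31,F,20,4,control
32,M,18,5,control
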