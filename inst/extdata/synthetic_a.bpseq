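1 U 0
2 A 0
3 A 0
4 G 0
5 C 0
6 U 0
7 C 0
8 U 0
9 U 34
10 C 33
11 C 32
12 U 31
13 G 0
14 U 25
15 A 24
16 A 0
17 C 0
18 A 0
19 U 0
20 C 0
21 U 0
22 U 0
23 U 0
24 U 15
25 A 14
26 U 0
27 G 0
28 C 0
29 C 0
30 A 0
31 A 12
32 G 11
33 G 10
34 A 9
35 G 64
36 C 63
37 U 62
38 U 61
39 G 60
40 A 59
41 A 0
42 G 0
43 C 0
44 U 0
45 C 0
46 A 52
47 A 51
48 U 0
49 C 0
50 U 0
51 U 47
52 U 46
53 U 0
54 C 0
55 A 0
56 U 0
57 A 0
58 U 0
59 U 40
60 C 39
61 A 38
62 G 37
63 G 36
64 C 35
65 C 0
66 C 0
67 C 0
68 A 0
69 C 0
70 A 0
71 C 0
72 C 0
73 A 0
74 C 0
75 G 0
76 A 0
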