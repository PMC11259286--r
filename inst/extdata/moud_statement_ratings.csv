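statement_id,mean_rating,n_raters
1,4.39,57
2,3.89,57
3,4.60,57
4,4.32,57
5,4.39,57
6,4.44,57
7,4.36,57
8,3.82,57
9,3.70,57
10,3.43,57
11,3.84,57
12,3.44,57
13,4.11,57
14,3.82,57
15,3.46,57
16,3.25,57
17,2.91,57
18,3.29,57
19,3.79,57
20,3.53,57
21,4.23,57
22,2.91,57
23,3.76,57
24,4.15,57
25,3.72,57
26,3.77,57
27,3.48,57
28,3.40,57
29,3.43,57
30,4.04,57
31,3.89,57
32,4.21,57
33,4.02,57
34,4.06,57
35,3.72,57
36,3.47,57
37,3.89,57
38,3.62,57
39,3.91,57
40,4.11,57
41,3.49,57
42,3.43,57
43,3.51,57
44,3.74,57
45,3.80,57
46,3.60,57
47,4.26,57
48,3.87,57
49,3.35,57
50,3.79,57
51,4.06,57
52,4.33,57
53,3.69,57
54,3.94,57
55,3.44,57
56,3.81,57
57,3.88,57
58,3.88,57
59,3.87,57
60,4.00,57
61,3.71,57
62,4.00,57
63,4.18,57
64,4.21,57
65,4.38,57
66,3.69,57
67,3.48,57
68,3.13,57
69,3.00,57
70,3.41,57
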