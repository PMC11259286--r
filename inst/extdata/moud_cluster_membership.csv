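"statement_id","cluster","cluster_label"
1,2,"Hopelessness and fear"
2,1,"Availability and accessibility"
3,3,"Basic needs not being met"
4,3,"Basic needs not being met"
5,1,"Availability and accessibility"
6,1,"Availability and accessibility"
7,1,"Availability and accessibility"
8,4,"Characteristics of treatment program"
9,4,"Characteristics of treatment program"
10,3,"Basic needs not being met"
11,1,"Availability and accessibility"
12,5,"Understanding and awareness of treatment"
13,6,"Personal motivations, attitudes, and beliefs"
14,2,"Hopelessness and fear"
15,6,"Personal motivations, attitudes, and beliefs"
16,6,"Personal motivations, attitudes, and beliefs"
17,7,"Easier to use drugs"
18,7,"Easier to use drugs"
19,4,"Characteristics of treatment program"
20,4,"Characteristics of treatment program"
21,3,"Basic needs not being met"
22,6,"Personal motivations, attitudes, and beliefs"
23,4,"Characteristics of treatment program"
24,4,"Characteristics of treatment program"
25,4,"Characteristics of treatment program"
26,1,"Availability and accessibility"
27,4,"Characteristics of treatment program"
28,7,"Easier to use drugs"
29,4,"Characteristics of treatment program"
30,1,"Availability and accessibility"
31,6,"Personal motivations, attitudes, and beliefs"
32,1,"Availability and accessibility"
33,5,"Understanding and awareness of treatment"
34,5,"Understanding and awareness of treatment"
35,5,"Understanding and awareness of treatment"
36,1,"Availability and accessibility"
37,7,"Easier to use drugs"
38,6,"Personal motivations, attitudes, and beliefs"
39,3,"Basic needs not being met"
40,1,"Availability and accessibility"
41,3,"Basic needs not being met"
42,2,"Hopelessness and fear"
43,6,"Personal motivations, attitudes, and beliefs"
44,3,"Basic needs not being met"
45,3,"Basic needs not being met"
46,3,"Basic needs not being met"
47,2,"Hopelessness and fear"
48,2,"Hopelessness and fear"
49,5,"Understanding and awareness of treatment"
50,4,"Characteristics of treatment program"
51,2,"Hopelessness and fear"
52,6,"Personal motivations, attitudes, and beliefs"
53,6,"Personal motivations, attitudes, and beliefs"
54,2,"Hopelessness and fear"
55,7,"Easier to use drugs"
56,3,"Basic needs not being met"
57,2,"Hopelessness and fear"
58,5,"Understanding and awareness of treatment"
59,7,"Easier to use drugs"
60,5,"Understanding and awareness of treatment"
61,2,"Hopelessness and fear"
62,2,"Hopelessness and fear"
63,5,"Understanding and awareness of treatment"
64,3,"Basic needs not being met"
65,2,"Hopelessness and fear"
66,7,"Easier to use drugs"
67,7,"Easier to use drugs"
68,5,"Understanding and awareness of treatment"
69,7,"Easier to use drugs"
70,5,"Understanding and awareness of treatment"
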