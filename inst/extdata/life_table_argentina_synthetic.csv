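age,qx
0,0.000522863259339479
1,0.00052528092276094
2,0.000527952847260926
3,0.000530905772204382
4,0.0005341692488261
5,0.000537775935884444
6,0.000541761926391549
7,0.000546167108687268
8,0.000551035565462876
9,0.000556416014720007
10,0.000562362297070296
11,0.000568933914239955
12,0.000576196624154313
13,0.000584223098543335
14,0.000593093649625676
15,0.000602897033120442
16,0.000613731335592171
17,0.000625704954970163
18,0.00063893768401091
19,0.000653561907488442
20,0.000669723925026733
21,0.000687585412725844
22,0.00070732503810933
23,0.000729140244427273
24,0.00075324922201836
25,0.000779893086271688
26,0.000809338283755734
27,0.000841879250313426
28,0.000877841347381336
29,0.000917584105501246
30,0.000961504806971547
31,0.00101004244286762
32,0.00106368208326912
33,0.00112295970349763
34,0.00118846751352319
35,0.00126085984248825
36,0.00134085963553532
37,0.00142926562588774
38,0.00152696025142307
39,0.00163491839187513
40,0.00175421701032785
41,0.00188604579088081
42,0.00203171887331943
43,0.00219268779535786
44,0.0023705557635969
45,0.00256709338578553
46,0.00278425600935128
47,0.00302420282448745
48,0.00328931790440146
49,0.0035822333706278
50,0.00390585488760464
51,0.00426338970796181
52,0.00465837750811204
53,0.00509472427267199
54,0.0055767395058085
55,0.00610917706758507
56,0.00669727995346359
57,0.00734682935488806
58,0.00806419835778949
59,0.00885641065320608
60,0.00973120464909272
61,0.0106971033836666
62,0.0117634906468285
63,0.0129406937155363
64,0.0142400730992089
65,0.0156741196695726
66,0.0172565595124079
67,0.0190024667822986
68,0.0209283847606995
69,0.0230524552063989
70,0.0253945559385117
71,0.0279764463968936
72,0.0308219206731363
73,0.0339569671851493
74,0.0374099337658695
75,0.0412116964358825
76,0.0453958295125055
77,0.0499987739537714
78,0.0550599999222983
79,0.0606221584570412
80,0.0667312158351336
81,0.0734365626662337
82,0.0807910879644693
83,0.0888512063689451
84,0.0976768243212388
85,0.107331228358357
86,0.11788087576231
87,0.129395064670456
88,0.141945457480343
89,0.155605428117278
90,0.170449200679629
91,0.186550744430981
92,0.203982388475007
93,0.222813119265385
94,0.24310652606053
95,0.264918364391747
96,0.288293716608796
97,0.313263742792808
98,0.339842036089271
99,0.368020625137664
100,1
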