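"age","qx_male","qx_female"
0,0.000524188864986878,0.00065234199338181
1,0.000525373025788668,0.000652397702444775
2,0.000526692524746413,0.000652462162890035
3,0.000528162829495249,0.000652536749478692
4,0.000529801175396875,0.000652623052933846
5,0.000531626767552796,0.000652722913866105
6,0.000533661005900375,0.000652838462028435
7,0.000535927736028511,0.000652972161737518
8,0.000538453528650793,0.000653126864430302
9,0.000541267991009342,0.000653305869476582
10,0.000544404113856155,0.000653512994544522
11,0.000547898658074919,0.000653752657019735
12,0.000551792585469864,0.000654029968214269
13,0.000556131538764601,0.000654350842374567
14,0.000560966376429022,0.000654722122813064
15,0.000566353768593002,0.000655151727853192
16,0.000572356861019036,0.000655648819700081
17,0.000579046014900557,0.000656223999838032
18,0.000586499631137453,0.000656889535121466
19,0.000594805068725555,0.000657659619380425
20,0.000604059667993856,0.000658550676118878
21,0.000614371890644524,0.000659581708760101
22,0.000625862589910315,0.000660774705906972
23,0.000638666425657321,0.00066215511025767
24,0.000652933440945167,0.000663752361173994
25,0.000668830818430997,0.000665600522469148
26,0.000686544837088781,0.000667739008797765
27,0.000706283052035157,0.000670213426131751
28,0.000728276722832948,0.000673076544235856
29,0.000752783518512261,0.000676389421868284
30,0.000780090530738269,0.000680222708683841
31,0.000810517630099203,0.000684658151578907
32,0.000844421204426069,0.00068979033756867
33,0.000882198322429442,0.000695728710319546
34,0.000924291370794664,0.00070259990327977
35,0.000971193218265753,0.000710550439081644
36,0.00102345296622598,0.000719749852671412
37,0.00108168235190996,0.000730394304620779
38,0.00114656287772455,0.000742710761476242
39,0.00121885374828506,0.000756961832026036
40,0.00129940070576726,0.000773451362260072
41,0.00138914586411707,0.000792530907854151
42,0.00148913865363819,0.000814607221557628
43,0.0016005479995874,0.000840150914284924
44,0.00172467587174796,0.000869706473443404
45,0.00186297235662711,0.000903903850575094
46,0.00201705242004156,0.000943471863321787
47,0.00218871454552326,0.000989253694698858
48,0.0023799614533046,0.00104222481643082
49,0.00259302312573068,0.00110351371351268
50,0.00283038238789064,0.00117442584518026
51,0.00309480331714169,0.00125647134419053
52,0.00338936278207505,0.00135139703295501
53,0.00371748544037114,0.00146122342300737
54,0.00408298255589274,0.00158828746504354
55,0.00449009502819307,0.00173529193202796
56,0.00494354106221291,0.00190536244944166
57,0.00544856894204271,0.00210211333662439
58,0.00601101540983314,0.00232972359340865
59,0.00663737018867107,0.00259302455899218
60,0.0073348472256953,0.00289760098736292
61,0.00811146326781539,0.00324990752754852
62,0.00897612441566575,0.00365740286916898
63,0.00993872132996908,0.00412870411530691
64,0.0110102337858272,0.00467376427572497
65,0.0122028452814327,0.00530407613266422
66,0.0135300684042661,0.00603290611543197
67,0.015006881634922,0.00687556222223473
68,0.0166498782199084,0.00784970043738031
69,0.0184774276621556,0.00897567449213841
70,0.020509850251728,0.0102769341829376
71,0.0227696048773134,0.0117804777545597
72,0.0252814901067603,0.0135173640266616
73,0.0280728581844515,0.0155232899170356
74,0.0311738411432645,0.0178392386954104
75,0.0346175876438089,0.0205122035531273
76,0.0384405084035374,0.0235959897173912
77,0.0426825271282117,0.0271520961371467
78,0.0473873326678503,0.0312506744121296
79,0.0526026266432475,0.035971557729975
80,0.0583803589771754,0.0414053456152057
81,0.0647769415624445,0.047654520652686
82,0.0718534276513668,0.0548345602661082
83,0.0796756414036941,0.0630749892118695
84,0.0883142383355302,0.0725202956741959
85,0.0978446731373782,0.0833306046369623
86,0.108347046468504,0.0956819655251946
87,0.119905796921468,0.109766066164898
88,0.132609198481348,0.125789131695211
89,0.146548617664504,0.143969706080729
90,0.161817478421603,0.164534948103331
91,0.178509877305698,0.187715008948793
92,0.196718787032684,0.213735005003003
93,0.216533784366213,0.242804073784764
94,0.238038239541209,0.275101027893811
95,0.261305910880495,0.310756236259626
96,0.286396901949883,0.349829609181311
97,0.313352962029204,0.392284997318521
98,0.342192146652399,0.437961989571813
99,0.372902906400849,0.486547050564996
100,0.405437741671368,0.537547172718337
101,0.439706650576711,0.590270644100714
102,0.475570706527269,0.643820927353794
103,0.512836228511082,0.697110592962068
104,0.551250143338977,0.748902125325991
105,0.590497271781604,0.79788044098548
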