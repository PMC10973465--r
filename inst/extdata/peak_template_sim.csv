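time_ms,B_pT
0,-0.0591181822
1,-0.0592328224
2,-0.0593499084
3,-0.059469556
4,-0.0595918894
5,-0.0597170411
6,-0.0598451535
7,-0.0599763789
8,-0.0601108814
9,-0.060248837
10,-0.0603904356
11,-0.0605358818
12,-0.0606853967
13,-0.0608392196
14,-0.0609976095
15,-0.0611608475
16,-0.0613292392
17,-0.0615031171
18,-0.0616828437
19,-0.061868815
20,-0.0620614641
21,-0.0622612655
22,-0.0624687398
23,-0.0626844595
24,-0.0629090545
25,-0.0631432193
26,-0.0633877204
27,-0.0636434049
28,-0.0639112096
29,-0.0641921716
30,-0.0644874388
31,-0.0647982825
32,-0.0651261093
33,-0.0654724742
34,-0.0658390932
35,-0.0662278556
36,-0.0666408348
37,-0.0670802974
38,-0.0675487087
39,-0.068048735
40,-0.0685832411
41,-0.069155282
42,-0.0697680882
43,-0.0704250443
44,-0.0711296578
45,-0.0718855186
46,-0.0726962442
47,-0.0735654093
48,-0.0744964541
49,-0.0754925671
50,-0.0765565353
51,-0.077690553
52,-0.0788959776
53,-0.0801730218
54,-0.0815203776
55,-0.0829347911
56,-0.0844106567
57,-0.0859397629
58,-0.0875113668
59,-0.0891127284
60,-0.0907300703
61,-0.0923497544
62,-0.0939593852
63,-0.0955486053
64,-0.0971094846
65,-0.0986365369
66,-0.100126472
67,-0.101577805
68,-0.102990421
69,-0.10436518
70,-0.105703597
71,-0.107007592
72,-0.108279288
73,-0.109520861
74,-0.110734435
75,-0.111922049
76,-0.113085661
77,-0.114227148
78,-0.115348282
79,-0.116450683
80,-0.11753579
81,-0.118604878
82,-0.119659126
83,-0.120699684
84,-0.121727701
85,-0.122744302
86,-0.123750527
87,-0.12474727
88,-0.125735268
89,-0.126715153
90,-0.127687534
91,-0.128653075
92,-0.129612521
93,-0.130566656
94,-0.131516221
95,-0.132461811
96,-0.133403816
97,-0.134342416
98,-0.135277632
99,-0.136209404
100,-0.137137664
101,-0.138062338
102,-0.138983286
103,-0.139900191
104,-0.140812421
105,-0.141718905
106,-0.142618051
107,-0.14350772
108,-0.144385256
109,-0.145247531
110,-0.146090985
111,-0.146911609
112,-0.14770487
113,-0.148465604
114,-0.14918791
115,-0.149865124
116,-0.150489939
117,-0.151054798
118,-0.151552585
119,-0.151977565
120,-0.152326312
121,-0.152598314
122,-0.152796017
123,-0.152924348
124,-0.152989893
125,-0.153
126,-0.152961999
127,-0.152882657
128,-0.15276787
129,-0.15262257
130,-0.152450786
131,-0.152255791
132,-0.152040284
133,-0.151806541
134,-0.151556512
135,-0.151291865
136,-0.151013984
137,-0.15072395
138,-0.150422523
139,-0.150110108
140,-0.149786734
141,-0.149452033
142,-0.149105267
143,-0.148745655
144,-0.148372434
145,-0.147984644
146,-0.147581024
147,-0.147159963
148,-0.146720185
149,-0.146261143
150,-0.145782547
151,-0.145284254
152,-0.144766152
153,-0.144228072
154,-0.14366975
155,-0.143090866
156,-0.142491129
157,-0.141870375
158,-0.141228645
159,-0.140566213
160,-0.139883562
161,-0.139181338
162,-0.138460284
163,-0.137721178
164,-0.136964788
165,-0.136191841
166,-0.13540301
167,-0.134598926
168,-0.133780167
169,-0.132947234
170,-0.132100498
171,-0.131240126
172,-0.130365921
173,-0.129477347
174,-0.128574698
175,-0.12765941
176,-0.126731514
177,-0.125788893
178,-0.124826798
179,-0.123846866
180,-0.122847838
181,-0.121820816
182,-0.120745479
183,-0.119591278
184,-0.118324662
185,-0.116884158
186,-0.114992166
187,-0.112238707
188,-0.10845152
189,-0.0999198047
190,-0.0849986549
191,-0.0747013624
192,-0.0669151215
193,-0.0604887823
194,-0.0545685724
195,-0.0487449001
196,-0.0438728988
197,-0.0384158436
198,-0.0334760759
199,-0.0279972566
200,-0.0226917319
201,-0.0162938232
202,-0.010399034
203,-0.00170475895
204,0.000889579095
205,0.00189511696
206,0.00318275865
207,0.00344129404
208,0.00496549322
209,0.00623532441
210,0.00675915059
211,0.00846914475
212,0.0101964776
213,0.0109076023
214,0.0123200111
215,0.0147597047
216,0.0156805358
217,0.0167789077
218,0.0195147951
219,0.0208550207
220,0.0218420325
221,0.0238400256
222,0.026228087
223,0.027270038
224,0.0285321027
225,0.0314565828
226,0.032870821
227,0.0339310282
228,0.0358728694
229,0.03846527
230,0.0395825488
231,0.0410947414
232,0.0439324194
233,0.0450255698
234,0.0458994642
235,0.0467591268
236,0.0476237449
237,0.0484965986
238,0.0493775434
239,0.0502651803
240,0.0511576189
241,0.0520528639
242,0.0529489976
243,0.0538442472
244,0.0547370053
245,0.0556258305
246,0.056509438
247,0.057386687
248,0.0582565667
249,0.0591181822
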