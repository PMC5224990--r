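index,code
1,C.3
2,C.2
3,C.ar
4,C.1
5,N.3
6,N.2
7,N.1
8,N.ar
9,N.am
10,N.pl3
11,N.4
12,O.3
13,O.2
14,O.co2
15,O.spc
16,O.t3p
17,S.3
18,S.2
19,S.o
20,S.o2
21,P.3
22,H
23,H.spc
24,H.t3p
25,F
26,Cl
27,Br
28,I
29,Li
30,Na
31,Mg
32,Al
33,Si
34,K
35,Ca
36,Cr.th
37,Cr.oh
38,Fe
39,Cu
40,Zn
41,Se
42,Sn
43,LP
44,Du
45,Du.C
46,Any
47,Hal
48,Het
49,Hev
50,C.cat
51,Mo
52,Mn
53,Co.oh
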