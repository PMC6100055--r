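"id","oral_ld50","inhalation_lc50","fish_lc50","bod_half_life","log_bcf"
1,"observed","observed","observed","observed","observed"
2,"observed","observed","observed","observed","observed"
3,"observed","observed","observed","observed","observed"
4,"observed","observed","observed","observed","observed"
5,"observed","observed","observed","observed","observed"
6,"observed","observed","observed","observed","observed"
7,"observed","observed","observed","observed","observed"
8,"observed","observed","observed","observed","observed"
9,"observed","observed","observed","observed","observed"
10,"observed","observed","observed","observed","observed"
11,"observed","observed","observed","observed","observed"
12,"observed","observed","observed","observed","observed"
13,"observed","observed","observed","observed","observed"
14,"observed","observed","observed","observed","observed"
15,"imputed","imputed","imputed","imputed","imputed"
16,"imputed","imputed","imputed","imputed","imputed"
17,"imputed","imputed","imputed","imputed","imputed"
18,"imputed","imputed","imputed","imputed","imputed"
19,"imputed","imputed","imputed","imputed","imputed"
20,"imputed","imputed","imputed","imputed","imputed"
21,"imputed","imputed","imputed","imputed","imputed"
22,"imputed","imputed","imputed","imputed","imputed"
23,"imputed","imputed","imputed","imputed","imputed"
24,"imputed","imputed","imputed","imputed","imputed"
25,"imputed","imputed","imputed","imputed","imputed"
26,"imputed","imputed","imputed","imputed","imputed"
27,"imputed","imputed","imputed","imputed","imputed"
28,"imputed","imputed","imputed","imputed","imputed"
29,"observed","imputed","observed","imputed","imputed"
30,"observed","observed","observed","observed","observed"
31,"observed","observed","observed","observed","observed"
32,"observed","observed","observed","observed","observed"
33,"observed","observed","observed","observed","observed"
34,"observed","observed","observed","observed","observed"
35,"observed","observed","observed","observed","observed"
36,"observed","observed","observed","observed","observed"
37,"observed","observed","observed","observed","observed"
38,"observed","observed","observed","observed","observed"
39,"observed","observed","observed","observed","observed"
40,"observed","imputed","imputed","imputed","observed"
41,"observed","observed","observed","observed","observed"
42,"observed","observed","observed","observed","observed"
43,"observed","observed","observed","observed","observed"
44,"observed","observed","observed","observed","observed"
45,"observed","observed","observed","observed","observed"
46,"observed","observed","observed","observed","observed"
47,"observed","observed","observed","observed","observed"
48,"observed","observed","observed","observed","observed"
49,"observed","observed","observed","observed","observed"
50,"observed","observed","observed","observed","observed"
51,"observed","observed","observed","observed","observed"
52,"observed","observed","observed","observed","observed"
53,"observed","observed","observed","observed","observed"
54,"observed","observed","observed","observed","observed"
55,"observed","observed","observed","observed","observed"
56,"observed","observed","observed","observed","observed"
57,"observed","observed","observed","observed","observed"
58,"observed","observed","observed","observed","observed"
59,"observed","observed","observed","observed","observed"
60,"observed","observed","observed","observed","observed"
61,"observed","observed","observed","observed","observed"
62,"observed","observed","observed","observed","observed"
63,"observed","observed","observed","imputed","observed"
64,"observed","imputed","imputed","observed","observed"
65,"observed","imputed","imputed","imputed","observed"
66,"observed","imputed","imputed","imputed","observed"
67,"observed","observed","observed","observed","observed"
68,"observed","observed","observed","observed","observed"
69,"observed","observed","observed","observed","observed"
70,"observed","observed","observed","observed","observed"
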