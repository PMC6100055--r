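"id","solvent","cas","oral_ld50","inhalation_lc50","fish_lc50","bod_half_life","log_bcf"
1,"Cyclopentane","287-92-3",11400,57377,100,10.6,1.61
2,"Octane","111-65-9",7930,25260,100,13.7,3.289
3,"Nonane","111-84-2",218,3200,6.5,16.4,2.651
4,"Decane","124-18-5",5000,1369,500,40,2.158
5,"Tridecane","629-50-5",5000,41,0.9,18.2,2.979
6,"Tetradecane","629-59-4",15000,5001,1000,38.7,3.036
7,"Pentadecane","629-62-9",5000,5001,100.1,39.6,2.34
8,"1-pentene","109-67-1",3197,21800,90.7,17,1.349
9,"1-hexene","646-04-8",10000,32000,5.6,10.7,1.91
10,"1-heptene","592-76-7",5000,27986,175,12.6,2.372
11,"1-octene","111-66-0",10000,8500,6.8,9.3,2.819
12,"1-nonene","124-11-8",4390,7116,5,9.6,3.266
13,"Pentanol","71-41-0",2200,6119,370,4,0.463
14,"oleic alcohol","143-28-2",9604,13049,46.7,9,2.623
15,"1,3-di-iso-propoxy-2-propanol","13021-54-0",1267,2725,33.5,1.6,0.5
16,"1,3-dimethoxypropan-2-ol","",1393,3794,104.7,2.5,0.5
17,"1,3-di-n-butoxy-2-propanol","",1130,885,69.4,2.1,0.603
18,"1-ethoxy-3-iso-propoxy-2-propanol","",1256,1889,377.7,4.3,0.5
19,"1-methoxy-3-(propan-2-yloxy)propan-2-ol","",1498,2945,160.8,2.1,0.5
20,"1-n-butoxy-3-ethoxy-2-propanol","",2220,2347,232.2,1.8,0.5
21,"1-n-butoxy-3-iso-propoxy-2-propanol","",3047,4273,188,1.5,0.168
22,"1-n-butoxy-3-methoxy-2-propanol","",1883,2582,197.6,2.1,0.5
23,"1-tert-butoxy-3-ethoxy-2-propanol","",2568,4601,97.1,1.3,0.5
24,"1-tert-butoxy-3-methoxy-2-propanol","",1477,3305,35.3,1.4,0.5
25,"3-butoxypropane-1,2-diol","",3875,2818,203.4,1.5,0.5
26,"3-ethoxypropane-1,2-diol","",2538,2663,186.2,1.9,0.5
27,"3-methoxypropane-1,2-diol","",2081,1985,272.4,2.6,0.5
28,"3-n-butoxy-1-tert-butoxy-2-propanol","",5660,5167,51.7,1.4,0.517
29,"Isopropylidene glycerol","100-79-8",7000,167197,16700,1.3,0.125
30,"Methoxycyclopentane","5614-37-9",1500,5250,34.9,6.6,0.721
31,"Benzyl ethyl ether","539-30-0",2428,2625,38.6,6.6,1.374
32,"1,2,3-trimethoxypropane","",1305,2815,135.8,5.3,0.5
33,"1,2,3-tri-n-butoxypropane","",4390,5001,261.2,4.5,2.276
34,"2-methylfuran","",1965,9352,94.3,16,0.725
35,"2-methyltetrahydrofuran","",4500,24083,319.6,6.4,0.343
36,"3-n-butoxy-1-tert-butoxy-2-methoxypropane","",2392,1656,95.4,2.9,1.094
37,"Isosorbide dimethyl ether","",1545,18269,213.8,4.9,0.5
38,"Dioxolane","646-06-0",2833,37363,31,6.1,0.149
39,"Benzaldehyde","100-52-7",1300,1304,1.07,10,1.1
40,"gamma-valerolactone","108-29-2",2800,1186,756.6,7.8,0.5
41,"Dihydrolevoglucosenone","",2021,2916,59.3,4.4,0.5
42,"1,8-cineole","470-82-6",2480,1000,102,26.4,1.41
43,"3-carene","13466-78-9",4800,8800,17.9,28,2.673
44,"Neryl acetate","141-12-8",4550,5001,41.7,8.7,2.365
45,"Propionic acid","79-19-4",3500,5422,51,1,0
46,"Ethyl formate","",1850,9800,276.6,15,0.5
47,"Butyl levulinate","2052-15-5",5000,5001,26.3,3.3,0.278
48,"Ethyl levulinate","539-88-8",5000,4735,121.3,3.3,0.5
49,"Glycerol triacetate","102-76-1",3000,5001,72.5,2.2,0.5
50,"Methyl caprylate","111-11-5",10800,9987,95,7,1.856
51,"Methyl lactate","27871-49-4",5000,1350,828.6,11.8,0.5
52,"Methyl levulinate","624-45-3",2051,2888,92.7,3.4,0.5
53,"Methyl linoleate","112-63-0",3977,5001,4.5,20.4,3.051
54,"Isopropyl myristate","110-27-0",8348,11207,8.4,10.7,3.07
55,"Methyl oleate","112-62-9",2000,5001,6.1,18.9,2.694
56,"Methyl palmitate","112-39-0",4786,5001,1.8,9.4,2.789
57,"Isopropyl palmitate","142-91-6",17781,45414,50.3,13,1.725
58,"Methyl stearate","112-61-8",5237,5001,2.8,10.4,1.46
59,"Tributyl 2-acetylcitrate","77-90-7",31500,226174,60,14,1.6
60,"Benzyl benzoate","120-51-4",1700,665,6.2,5.3,2.357
61,"cis-1,2-dichloroethene","156-59-2",1393,13700,54.2,180,1.18
62,"1,1-dichloroethane","75-34-3",725,13000,100,154,1.24
63,"1,1,1,2-tetrachloroethane","630-20-6",670,2100,20,134,1.559
64,"1-chloropropane","540-54-5",2000,14034,117.8,30,0.763
65,"1-chlorobutane","109-69-3",2670,11879,101.2,18.2,1.333
66,"1-chloropentane","543-59-9",3379,11804,27.8,10.5,1.402
67,"Dimethyl sulphide","75-18-3",535,5156,87.1,10.7,0.561
68,"Dimethyl sulfoxide","67-68-5",2758,4291,36.9,1.6,0.349
69,"Diethylamine","109-89-7",540,4000,218.5,5,0.21
70,"2-pyrrolidone","616-45-5",2030,1083,152.5,2.5,0.5
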