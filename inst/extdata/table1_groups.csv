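index,name,class,habitat,stanza,tl,biomass,z,pb,qb,ee,pq,ba,landings_artisanal,landings_demersal,landings_pelagic,estimated
1,Marine mammals,consumer,migratory,none,4.16,0.01,,0.04,12.5,0.000,0.003,0,0,0,0,tl;ee;pq
2,Coastal birds,consumer,migratory,none,3.44,0.01,,0.28,67.0,0.000,0.004,0,0,0,0,tl;ee;pq
3,Meagre ad,consumer,migratory,adult,3.94,0.12,0.21,,2.1,0.657,0.100,0,0.007,0.007,0,tl;ee;pq
4,Meagre juv,consumer,migratory,juvenile,3.80,5e-05,0.3,,17.9,0.974,0.017,0,0,0,0,tl;biomass;qb;ee;pq
5,Mullets,consumer,migratory,none,2.10,0.42,,0.8,8.2,0.800,0.097,0,0.04,0.063,0,tl;biomass;pq
6,Pelagic L,consumer,pelagic,none,3.84,3.42,,0.96,5.4,0.900,0.178,0,0.008,0,2.671,tl;biomass;pq
7,Mackerel,consumer,pelagic,none,3.20,1.45,,0.45,3.0,0.735,0.150,0,0,0,0.289,tl;ee;pq
8,Sardine,consumer,pelagic,none,2.90,11.79,,0.65,4.3,0.771,0.150,0,0,0,1.801,tl;ee;pq
9,Sardinelles,consumer,pelagic,none,2.78,18,,0.99,7.7,0.785,0.129,0,0.108,0,2.202,tl;ee;pq
10,Horse mackerels,consumer,pelagic,none,3.23,10,,0.72,3.6,0.844,0.200,0,0.003,0,3.809,tl;qb;ee
11,Coastal selacians,consumer,coastal,none,3.64,1.24,,0.3,2.0,0.015,0.150,-0.05,0.046,0.017,0,tl;qb;ee
12,Coastal M,consumer,coastal,none,3.05,0.83,,0.58,2.9,0.858,0.200,0,0.053,0.068,0,tl;qb;ee
13,Coastal S,consumer,coastal,none,3.12,4.21,,0.62,3.1,0.950,0.200,0,0,0,0,tl;biomass;qb
14,Croakers ad,consumer,coastal,adult,3.66,0.077,0.6,,3.9,0.754,0.156,0,0.001,0.002,0,tl;ee;pq
15,Croakers juv,consumer,coastal,juvenile,3.23,0.004,1.17,,9.9,0.706,0.118,0,0,0,0,tl;ee;pq
16,Seabreams ad,consumer,coastal,adult,3.15,1.69,0.48,,4.7,0.884,0.102,0,0.044,0.123,0,tl;ee;pq
17,Seabreams juv,consumer,coastal,juvenile,3.14,0.012,0.76,,21.1,0.884,0.036,0,0,0,0,tl;ee;pq
18,Catfish ad,consumer,coastal,adult,3.48,0.6,0.34,,4.1,0.226,0.083,0,0.034,0,0,tl;ee;pq
19,Catfish juv,consumer,coastal,juvenile,3.05,0.002,0.58,,22.3,0.780,0.026,0,0,0,0,tl;ee;pq
20,Shelf selacians,consumer,shelf,none,4.06,0.2,,0.24,1.6,0.787,0.150,0,0.001,0.01,0,tl;qb;ee
21,Shelf L,consumer,shelf,none,4.08,0.36,,0.47,3.4,0.467,0.140,0,0,0.071,0,tl;ee;pq
22,Shelf M,consumer,shelf,none,3.24,1.55,,0.57,6.2,0.908,0.092,0,0.01,0.136,0,tl;ee;pq
23,Groupers ad,consumer,shelf,adult,3.78,0.11,0.43,,3.2,0.938,0.137,-0.05,0.017,0.008,0,tl;ee;pq
24,Grouper juv,consumer,shelf,juvenile,3.53,0.0004,0.44,,16.2,0.536,0.027,-0.05,0,0,0,tl;ee;pq
25,Sparids ad,consumer,shelf,adult,2.96,1.29,0.44,,2.4,0.871,0.186,0,0.009,0.005,0,tl;ee;pq
26,Sparids juv,consumer,shelf,juvenile,2.60,0.01,0.86,,9.8,0.939,0.088,0,0,0,0,tl;ee;pq
27,Scianids,consumer,shelf,none,3.42,0.22,,0.29,4.3,0.665,0.068,-0.05,0.001,0.016,0,tl;ee;pq
28,Shelf soles,consumer,shelf,none,3.31,0.35,,0.58,2.9,0.882,0.200,0,0.001,0.008,0,tl;qb;ee
29,Shelf S,consumer,shelf,none,3.05,6.195,,0.82,7.6,0.950,0.108,0,0,0.005,0,tl;biomass;pq
30,Octopus vulgaris,consumer,shelf,none,3.15,1.37,,1.4,4.7,0.632,0.300,-0.03,0.218,0.665,0,tl;qb;ee
31,Cephalopods,consumer,shelf,none,3.56,1,,1.2,4.0,0.839,0.300,-0.03,0.001,0.254,0,tl;qb;ee
32,BA L crustaceans,consumer,banc_sedentary,none,2.43,9.12,,1.44,7.2,0.877,0.200,0,0,0,0,tl;qb;ee
33,BA molluscs,consumer,banc_sedentary,none,2.05,17.86,,1.5,16.7,0.888,0.090,0,0,0,0,tl;qb;ee
34,BA worms,consumer,banc_sedentary,none,2.03,5.32,,3,33.3,0.805,0.090,0,0,0,0,tl;qb;ee
35,BA crustaceans,consumer,banc_sedentary,none,2.10,1.14,,2.4,12.0,0.975,0.200,0,0,0,0,tl;qb;ee
36,BA other inverts,consumer,banc_sedentary,none,2.21,0.57,,1.8,9.0,0.868,0.200,0,0,0,0,tl;qb;ee
37,BA meiobenthos,consumer,banc_sedentary,none,2.00,2.09,,9,100.0,0.930,0.090,0,0,0,0,tl;qb;ee
38,shelf L crustaceans,consumer,shelf_sedentary,none,2.52,8.1,,1.5,7.5,0.732,0.200,0,0.001,0.004,0,tl;ee;pq
39,shelf molluscs,consumer,shelf_sedentary,none,2.00,26.21,,1.5,16.7,0.500,0.090,0,0,3e-06,0,tl;qb;ee
40,shelf worms,consumer,shelf_sedentary,none,2.00,31.77,,3,33.0,0.409,0.091,0,0,0,0,tl;ee;pq
41,shelf crustaceans,consumer,shelf_sedentary,none,2.10,8.04,,2.4,12.0,0.797,0.200,0,0,0,0,tl;ee;pq
42,shelf other inverts,consumer,shelf_sedentary,none,2.10,17.21,,1.8,9.0,0.224,0.200,0,0,0,0,tl;ee;pq
43,shelf meiobenthos,consumer,shelf_sedentary,none,2.00,8.91,,9,100.0,0.253,0.090,0,0,0,0,tl;qb;ee
44,mesozoopl.,consumer,shelf_sedentary,none,2.00,55.08,,24,112.0,0.146,0.214,0,0,0,0,tl;ee;pq
45,macrozoopl.,consumer,shelf_sedentary,none,2.40,3.41,,4.3,17.0,0.728,0.253,0,0,0,0,tl;ee;pq
46,BA mesozoopl.,consumer,banc_sedentary,none,2.00,1.78,,24,112.0,0.800,0.214,0,0,0,0,tl;biomass;pq
47,BA macrozoopl.,consumer,banc_sedentary,none,2.40,2.5,,4.3,17.0,0.800,0.253,0,0,0,0,tl;biomass;pq
48,BA phytopl.,producer,banc_sedentary,none,1,5.9,,100,0,0.260,0,0,0,0,0,tl;ee
49,phytoplankton,producer,producer,none,1,67.8,,100,0,0.853,0,0,0,0,0,tl;ee
50,algae and eelgrass,producer,producer,none,1,548.8,,4.06,0,0.011,0,0,0,0,0,tl;ee
51,Detritus,detritus,detritus,none,1,560,,0,0,0.455,0,0,0,0,0,tl;ee
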