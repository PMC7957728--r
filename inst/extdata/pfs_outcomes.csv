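patient_id,treatment,pfs_months,progressed
1,ipilimumab_nivolumab,1.5,1
2,ipilimumab_nivolumab,17.9,0
3,ipilimumab_nivolumab,4.0,1
4,ipilimumab_nivolumab,3.2,1
5,ipilimumab_nivolumab,0.4,1
6,ipilimumab_nivolumab,19.3,0
7,ipilimumab_nivolumab,38.7,0
8,ipilimumab_nivolumab,18.3,0
9,ipilimumab_nivolumab,21.2,0
10,ipilimumab_nivolumab,24.2,0
11,nivolumab,6.2,1
12,pembrolizumab,11.0,1
13,pembrolizumab,2.0,1
14,ipilimumab_nivolumab,17.8,1
15,pembrolizumab,42.1,0
16,pembrolizumab,14.6,1
17,nivolumab,9.6,1
18,pembrolizumab,1.9,1
19,pembrolizumab,5.9,1
20,pembrolizumab,1.5,1
21,ipilimumab_nivolumab,17.0,1
22,ipilimumab_nivolumab,12.1,1
23,pembrolizumab,0.9,1
24,nivolumab,1.1,1
25,nivolumab,2.7,1
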