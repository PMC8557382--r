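pair_id,tree_1,tree_2,sc,pair_slenderness
1,40_24,60_20,0.70,0.65
2,60_22,80_21,0.39,0.50
3,60_22,60_21,0.13,0.53
4,80_22,60_21,0.26,0.45
5,60_20,60_21,0.47,0.50
6,60_20,80_22,0.15,0.43
7,40_25,80_22,0.63,0.60
8,60_06,100_05,0.70,0.55
9,40_06,100_05,0.75,0.58
10,40_10,60_08,0.67,0.74
11,40_11,60_08,0.40,0.64
12,40_10,40_11,0.68,0.76
13,40_12,60_12,0.65,0.66
14,80_05,60_12,0.20,0.48
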