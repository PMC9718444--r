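age_group_label,population
0-4,4988
5-9,5300
10-14,5599
15-19,6008
20-24,5968
25-29,6410
30-34,7291
35-39,8316
40-44,9732
45-49,8663
50-54,8018
55-59,7621
60-64,8552
65-69,9759
70+,23021
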