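patient	explained	total
Breast 1	526	1336
Breast 2	719	1411
Breast 3	177	367
Head & Neck 1	275	930
Head & Neck 2	179	674
Head & Neck 3	217	993
Lung 1	56	233
Lung 2	47	155
Lung 3	11	167
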