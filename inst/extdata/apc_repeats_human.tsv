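index	start	end
1	1262	1281
2	1376	1395
3	1486	1505
4	1558	1577
5	1863	1882
6	2007	2026
7	2034	2053
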