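chrom	start_mb	end_mb
1A	213.0	219.2
2A	346.2	352.1
3A	332.0	338.2
4A	288.5	295.0
5A	253.0	260.0
6A	285.7	293.5
7A	368.0	373.6
1B	236.0	243.3
2B	366.3	373.0
3B	362.0	365.2
4B	328.6	334.7
5B	210.0	215.0
6B	346.2	351.8
7B	314.2	320.3
1D	172.8	180.0
2D	269.8	276.5
3D	252.2	258.0
4D	186.6	191.6
5D	193.2	199.3
6D	239.0	244.8
7D	347.6	353.0
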