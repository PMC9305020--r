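>NR_DR1_syn
0.850 0.050 0.050 0.050
0.050 0.050 0.850 0.050
0.050 0.050 0.850 0.050
0.050 0.050 0.050 0.850
0.050 0.850 0.050 0.050
0.850 0.050 0.050 0.050
0.850 0.050 0.050 0.050
0.850 0.050 0.050 0.050
0.050 0.050 0.850 0.050
0.050 0.050 0.850 0.050
0.050 0.050 0.050 0.850
0.050 0.850 0.050 0.050
0.850 0.050 0.050 0.050
>PAL_syn
0.050 0.050 0.850 0.050
0.050 0.050 0.850 0.050
0.050 0.050 0.850 0.050
0.850 0.050 0.050 0.050
0.850 0.050 0.050 0.050
0.050 0.050 0.050 0.850
0.050 0.050 0.050 0.850
0.050 0.850 0.050 0.050
0.050 0.850 0.050 0.050
0.050 0.850 0.050 0.050
>LOWINFO_syn
0.200 0.300 0.300 0.200
0.300 0.200 0.200 0.300
0.200 0.300 0.300 0.200
0.300 0.200 0.200 0.300
0.200 0.300 0.300 0.200
0.300 0.200 0.200 0.300
0.200 0.300 0.300 0.200
0.300 0.200 0.200 0.300
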