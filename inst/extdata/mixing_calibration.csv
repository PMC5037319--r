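sample_id,true_human_pct,replicate,mapped_human_pct,mapped_mouse_pct,printed_estimate
0_100_R1,0,1,0.10,99.90,0.00
0_100_R2,0,2,0.10,99.90,0.01
0_100_R3,0,3,0.08,99.92,0.01
25_75_R1,25,1,62.44,37.56,22.55
25_75_R2,25,2,64.58,35.42,24.36
50_50_R1,50,1,83.14,16.86,52.59
50_50_R2,50,2,82.18,17.82,50.56
50_50_R3,50,3,82.78,17.22,51.82
90_10_R2,90,1,97.59,2.41,90.97
90_10_R3,90,2,97.58,2.42,90.93
100_0_R1,100,1,99.98,0.02,98.70
100_0_R2,100,2,99.98,0.02,98.69
100_0_R3,100,3,99.98,0.02,98.70
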