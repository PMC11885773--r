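control,step_nm,step_se_nm
2.5,13.993,0.25
3,12.897,0.25
3.5,11.89,0.25
4,11.408,0.25
4.5,10.216,0.25
5,9.531,0.25
5.5,7.822,0.25
6,7.012,0.25
6.5,5.574,0.25
7,5.171,0.25
7.5,4.207,0.25
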