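volunteer,gm_epi,gm_spark,wm_epi,wm_spark,csf_epi,csf_spark,other_epi,other_spark
V1,64.33,73.01,20.71,18.75,11.06,8.05,3.9,0.19
V2,65.63,75.28,15.26,17.55,18.34,7.05,0.77,0.12
V3,60.04,62.53,16.27,26.49,16.13,10.84,7.56,0.14
V4,70.90,63.98,15.84,28.57,13.08,7.37,0.18,0.08
V5,60.58,86.57,30.94,10.09,8.27,3.34,0.25,0
V6,65.12,64.71,27.97,31.77,6.7,3.4,0.21,0.12
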