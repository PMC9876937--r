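model,aicc,delta_aicc,evidence_ratio
M1,-2941.849,0.000,1.000
M2,-2939.834,2.015,2.738
M3,-2939.112,2.736,3.928
M4,-2937.938,3.911,7.068
M5,-2937.060,4.789,10.964
M6,-2936.062,5.787,18.054
M7,-2936.036,5.812,18.287
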