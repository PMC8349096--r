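arm,centromeric_reference,centromeric_detected,telomeric_reference,telomeric_detected
X,20.67,20.10,2.46,0.92
2L,19.95,20.33,0.70,0.68
2R,6.09,5.01,20.02,20.71
3L,18.41,20.30,0.36,2.26
3R,8.35,3.77,27.25,25.64
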