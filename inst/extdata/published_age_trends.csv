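dimension,band,deviation
GH,18-24,0
GH,25-34,-0.07
GH,35-44,-0.42
GH,45-54,-0.59
GH,55-64,-0.84
GH,65-74,-1.12
GH,75-84,-1.40
PF,18-24,0
PF,25-34,-0.60
PF,35-44,-1.19
PF,45-54,-2.38
PF,55-64,-3.58
PF,65-74,-4.77
PF,75-84,-5.96
MH,18-34,0
MH,35-44,-0.09
MH,45-64,-0.19
MH,65-74,-0.28
MH,75-84,-0.56
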