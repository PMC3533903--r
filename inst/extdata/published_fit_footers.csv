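dimension,sigma2_0,k0,sigma2,k,n
GH,1.4272,37,1.2406,50,26388
PF,9.3182,21,6.8119,30,26388
MH,1.8377,46,1.7436,54,26388
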