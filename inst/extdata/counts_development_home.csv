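# bptriage zone-phenotype counts v1, arm=home, n=256
phenotype,normotension,intermediate,hypertension
NT,24,23,0
WH,0,17,4
MH,9,31,0
SH,0,76,72
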