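# bptriage zone-phenotype counts v1, arm=home, n=399
phenotype,normotension,intermediate,hypertension
NT,10,45,0
WH,0,18,0
MH,10,59,0
SH,0,140,117
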