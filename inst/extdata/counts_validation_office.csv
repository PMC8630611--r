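# bptriage zone-phenotype counts v1, arm=office, n=399
phenotype,normotension,intermediate,hypertension
NT,12,33,0
WH,0,19,10
MH,4,58,0
SH,0,88,175
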