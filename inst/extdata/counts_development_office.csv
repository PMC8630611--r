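# bptriage zone-phenotype counts v1, arm=office, n=256
phenotype,normotension,intermediate,hypertension
NT,14,34,0
WH,0,13,7
MH,2,40,0
SH,0,38,108
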