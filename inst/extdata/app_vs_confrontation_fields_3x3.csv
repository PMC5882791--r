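"","positive","negative","unable"
"positive",15,4,1
"negative",6,20,1
"unable",2,0,0
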