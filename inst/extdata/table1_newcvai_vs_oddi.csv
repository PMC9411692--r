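,normal,mild,moderate,severe
normal,12,2,0,0
mild,5,10,6,0
moderate,0,5,13,4
severe,0,0,1,2
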