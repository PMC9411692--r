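,normal,mild,moderate,severe
normal,24,3,0,0
mild,4,10,2,0
moderate,0,6,8,1
severe,0,0,0,2
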