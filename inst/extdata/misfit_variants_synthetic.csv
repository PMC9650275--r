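variant,factor
none,1
T17-weak,0.8
T17-medium,0.45
T17-strong,0.15
T17-perfect,0.02
off,0
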