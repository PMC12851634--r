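name: 2010s
T_mean: 14.3
amplitude: 5.25
omega: 187
GS: 250
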