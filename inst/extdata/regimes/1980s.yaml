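name: 1980s
T_mean: 12.85
amplitude: 5.3
omega: 187
GS: 250
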