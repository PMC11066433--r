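type: extended_params
alpha: 3.0
beta: 5.0
gamma: 3.5
Kalpha: 10.1
Kbeta: 5.0
K1t: 0.46
K2t: 0.62
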