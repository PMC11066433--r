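type: core_params
a: 2.36
b: 0.33
c: 3.5
d1: 1.0
d2: 1.0
d3: 1.0
Ka: 0.016
Kb: 0.002
K1: 0.46
K2: 0.62
na: 1.6
nb: 1.7
note: >
  a/d1, b/d2, Ka, Kb, na, nb come from the dose-response fit of the
  steady-state curves; c/d3, K1, K2 are NOT determined by that fit
  (the imaging-scale K1 scans use an unspecified c/d3) and are populated
  here with the endogenous-model values gamma, K1-tilde, K2-tilde.
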