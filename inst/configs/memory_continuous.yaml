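# Continuous low-dose exposure under the memory mechanism: two decline
# phases of the unaltered pool, ending with every cell permanently altered.
model: memory
params:
  alpha: 0.1
  p: 0.05
  c: 1
  eta: 0.01
initial: {x: 100, y: 0, w: 0, z: 0}
output: {t_end: 1.0e+5, n: 400}
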