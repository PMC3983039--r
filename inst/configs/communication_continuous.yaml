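# Continuous exposure with bystander communication (beta0 = 10): a
# quasi-stationary plateau separates the initial and final declines.
model: communication
params:
  alpha: 0.1
  p: 0.05
  c: 1
  eta: 0.01
  beta0: 10
  beta1: 0
initial: {x: 100, y: 0, w: 0, z: 0}
output: {t_end: 1.0e+6, n: 600}
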