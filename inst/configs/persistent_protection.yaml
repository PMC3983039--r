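# Adapted cells recruit healthy cells (beta1 = 1): after radiation stops
# the protected pool self-maintains and x settles at eta / beta1.
model: communication
params: {p: 0.05, c: 1, eta: 0.01, beta0: 10, beta1: 1}
schedule:
  - {t_start: 0,  t_end: 10, alpha: 0.1, p: 0.05}
  - {t_start: 20, t_end: 25, alpha: 100, p: 0.05}
initial: {x: 100}
output: {t_end: 5000, n: 400}
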