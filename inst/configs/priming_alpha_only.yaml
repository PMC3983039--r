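# Priming then challenge where dose only raises the hit rate: priming can
# not reduce the number of altered cells.
model: memory
params: {p: 0.05, c: 1, eta: 0.01}
schedule:
  - {t_start: 0,  t_end: 10, alpha: 0.1, p: 0.05}
  - {t_start: 20, t_end: 25, alpha: 100, p: 0.05}
initial: {x: 100}
output: {t_end: 200, n: 300}
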