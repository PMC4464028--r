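# Validation experiment on the logistic fixture, mirroring the first
# benchmark row of the standard settings (n = 1000, +/-25%, T = [0, 50],
# 50 points, r = 4).
model: logistic
seed: 20201
n: 1000
var_pct: 25
r: 4
alpha: 0.01
time:
  t_ini: 0
  t_end: 50
  points: 50
key_parameters: [r]
plots:
  scale: linear
  formats: [png]
output_dir: results/logistic
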