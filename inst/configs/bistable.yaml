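# Validation experiment on the bistable toy fixture, mirroring the second
# benchmark row (n = 1000, +/-30% around p = 0.5, T = [0, 500], 500 points,
# r = 4), including a bifurcation scan in p.
model: bistable_toy
seed: 20202
n: 1000
var_pct: 30
r: 4
alpha: 0.01
time:
  t_ini: 0
  t_end: 500
  points: 500
key_parameters: [p]
bifurcation:
  parameter: p
  range: [0.1, 0.9]
  points: 81
plots:
  scale: linear
  formats: [png]
output_dir: results/bistable
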