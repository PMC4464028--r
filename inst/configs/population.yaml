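# Standard experiment for the CSC population model: n = 1000 uniform LHS
# samples, +/-50% variation around the package baselines, T = [0, 200] with
# 200 points, r = 4 levels. P_sy spans its full probability range [0, 1].
# Baselines are package defaults constructed to satisfy the documented
# qualitative constraints; they are not measured ground truth.
model: csc
seed: 20200
n: 1000
var_pct: 50
r: 4
alpha: 0.01
time:
  t_ini: 0
  t_end: 200
  points: 200
key_parameters: [P_sy, omega_CSC, eta_1]
combinations:
  - "P_sy*omega_CSC"
  - "P_sy*omega_CSC-eta_1"
bifurcation:
  parameter: P_sy
  range: [0, 1]
  points: 101
plots:
  scale: log
  formats: [png]
output_dir: results/population
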