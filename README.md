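# cscsense

Global sensitivity and bifurcation analysis for ODE models of
hierarchically structured tumors, built around a five-compartment cancer
stem cell (CSC) population model with feedback-limited proliferation.

Many ODE models in systems biology have more uncertain parameters than the
data can pin down. `cscsense` implements a three-phase exploration
workflow for such models:

1. **Input/output characterization** — Latin hypercube sampling (LHS) of
   the parameter space (one sample per equal-probability stratum, per
   parameter) and batch integration of the model over a time grid,
   assembling the output matrix *Y* (samples x times x variables).
2. **Key-parameter identification** — time-course partial rank
   correlation coefficients (PRCC) between every parameter and every
   output variable, with Student-t significance tests and the
   non-significant band marked on the plots.
3. **Key-parameter analysis** — the range of a key parameter is split
   into *r* equal color-coded levels (black/blue/red/green for *r* = 4);
   trajectories and end-point scatter plots are colored by level, derived
   parameter combinations (e.g. `P_sy*omega_CSC-eta_1`) are first-class
   axes, and a one-parameter bifurcation scan classifies equilibria via
   Jacobian eigenvalues and locates transcritical points by bisection.

The workflow is model-agnostic (any ODE system registered through
`modelDefinition()`); the shipped application is the CSC tumor model.

## The model

Five compartments: cancer stem cells (CSC), two progenitor levels (PC1,
PC2), terminal cells (TC) and dead cells (DC):

```
dN_CSC/dt = P_sy W_C N_CSC + gamma_PC N_PC1 - (eta_1 + delta_1) N_CSC
dN_PC1/dt = (1 - P_sy) W_C N_CSC - W_P N_PC1 - gamma_PC N_PC1
            + eta_1 N_CSC - (eta_2 + delta_2) N_PC1
dN_PC2/dt = 2 W_P N_PC1 + eta_2 N_PC1 - (eta_3 + delta_2) N_PC2
dN_TC/dt  = eta_3 N_PC2 - delta_3 N_TC
dN_DC/dt  = delta_1 N_CSC + delta_2 (N_PC1 + N_PC2) + delta_3 N_TC
            - delta_4 N_DC
```

with feedback-limited proliferation rates
`W_C = omega_CSC / (1 + h_CSC N_TC)` and
`W_P = omega_PC / (1 + h_PC N_TC)`: the terminal-cell mass depresses
division, bounding tumor growth. A CSC divides symmetrically (two CSCs)
with probability `P_sy`; PC1 division produces two PC2 cells.

The trivial equilibrium (no tumor) is stable iff
`P_sy < P* = (eta_1 + delta_1) / omega_CSC` — the **tumor invasion
boundary**. At `P*` the zero and positive equilibria exchange stability
(a transcritical bifurcation): below it tumors die out, above it they
grow to a feedback-limited plateau. `invasionThreshold()` evaluates the
closed form; `scanParameter()` finds the crossing numerically.

The shipped baseline parameters are a documented package choice (see the
methods vignette), not measured ground truth; they satisfy `P* = 0.025`
and the documented qualitative constraints.

## Worked example

```r
library(cscsense)

design <- lhsSample(cscParameterSpecs(), n = 200, seed = 1)
Y <- simulateEnsemble("csc", design, grid = timeGrid(0, 200, points = 200))
Y
#> <ensembleOutput> 200 samples x 200 times x 5 variables (N_CSC, N_PC1, N_PC2, N_TC, N_DC)
#>   time interval [0, 200], 200/200 successful runs

sens <- prccOverTime(design, collapseProgenitors(Y))
sens
#> <sensitivityResult> 200 times x 13 parameters x 4 variables
#>   n_effective = 200, alpha = 0.01, critical |PRCC| = 0.187
#>   top |PRCC| at t = 200: P_sy = 0.972, omega_CSC = 0.774, h_CSC = 0.710, delta_3 = 0.579, delta_4 = 0.575

diag <- scanParameter("csc", unclass(cscParameters(gamma_PC = 0)),
                      name = "P_sy", range = c(0, 1), n_points = 21,
                      y0 = cscInitialState())
diag
#> <bifurcationDiagram> parameter P_sy over [0, 1], 21 points
#>   branches: nontrivial (21 pts), trivial (21 pts)
#>   transcritical point(s) at 0.0249996

ext <- extinctAtEnd(Y)   # final N_CSC below its initial value
lv <- assignLevel(design$matrix$P_sy, partitionRange(0, 1, 4, parameter = "P_sy"))
tapply(ext, lv, mean)
#>    1    2    3    4
#> 0.48 0.10 0.00 0.00
```

Reading the output: the symmetric-division probability `P_sy` carries the
strongest monotone association with every subpopulation at the end of the
course (|PRCC| 0.97, far above the 0.187 significance band); the scan
puts the transcritical point at 0.025, matching the closed form
`(eta_1 + delta_1)/omega_CSC`; and extinction is concentrated in the
lowest `P_sy` color level (48% of black-level samples fail to grow, 10%
of blue, none of red or green) — the switch between unsustainable growth
and tumorigenesis.

Full pipelines are driven by YAML configs (see `inst/configs/`) through
`runWorkflow()` or the CLI:

```sh
inst/cli/cscsense run --config inst/configs/population.yaml --out results/population
inst/cli/cscsense bifurcate --model csc --param P_sy --range 0:1 --points 201 --out diagram.csv
```

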