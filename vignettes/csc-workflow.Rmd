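---
title: "Exploring a feedback-limited cancer stem cell model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring a feedback-limited cancer stem cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscsense)
```

# The model and its assumptions

`cscsense` ships a deterministic ODE model of a hierarchically structured
tumor. Five compartments are tracked: cancer stem cells (`N_CSC`), two
progenitor levels (`N_PC1`, `N_PC2`, reported jointly as
`N_PC = N_PC1 + N_PC2`), terminal cells (`N_TC`) and dead cells
(`N_DC`). The biological picture is a lineage: CSCs self-renew and feed
progenitors, progenitors amplify and differentiate into terminal cells,
and all death fluxes accumulate in a dead-cell pool cleared by lysis.
Three assumptions matter:

* **Division bookkeeping.** A CSC division is symmetric (two CSCs) with
  probability `P_sy` and asymmetric otherwise, in which case the
  daughter enters PC1. A PC1 division produces two PC2 cells, which is
  why the PC2 gain term is `2 W_P N_PC1` while PC1 carries the matching
  loss `-W_P N_PC1`. PC1 cells can also de-differentiate back into the
  CSC pool at rate `gamma_PC`.
* **Feedback-limited proliferation.** The microenvironment bounds
  division through the terminal-cell mass: both proliferation rates are
  scaled as `omega / (1 + h * N_TC)` (`effectiveRate()`), with feedback
  intensities `h_CSC`, `h_PC` in units of 1/cells. This is the only
  nonlinearity; without it the system is linear and unbounded.
* **Autonomy.** The right-hand side does not depend on time; `t` is
  accepted in the `rhs` contract purely for solver compatibility.

The CSC equation at low density has net rate
`P_sy * omega_CSC - eta_1 - delta_1` (plus the `gamma_PC` coupling), so
the zero state loses stability at the **invasion boundary**
`P* = (eta_1 + delta_1) / omega_CSC`. This closed form ignores
de-differentiation: with `gamma_PC > 0` the CSC and PC1 rows of the
Jacobian couple at the origin and the true crossing shifts slightly.
`invasionThreshold()` implements the closed form verbatim and attaches a
warning when `gamma_PC > 0`; `scanParameter()` reports the numerically
exact crossing, so both readings are available without guessing which is
intended.

# Baseline parameters: a constructed, documented choice

The baselines shipped in `cscParameters()` are **package defaults, not
measurements**. They were constructed once, to satisfy a set of
qualitative constraints, and then frozen:

| parameter | default | unit | role |
|---|---|---|---|
| `P_sy` | 0.5 | – | probability of symmetric CSC division (sampled over [0, 1]) |
| `omega_CSC` | 1.0 | 1/day | CSC proliferation |
| `omega_PC` | 0.8 | 1/day | PC1 proliferation |
| `eta_1, eta_2, eta_3` | 0.01, 0.2, 0.3 | 1/day | CSC, PC1, PC2 differentiation |
| `gamma_PC` | 0.01 | 1/day | PC1 de-differentiation |
| `delta_1, delta_2, delta_3` | 0.015, 0.05, 0.01 | 1/day | CSC, PC, TC death |
| `delta_4` | 0.2 | 1/day | dead-cell lysis |
| `h_CSC, h_PC` | 1.5e-4 | 1/cells | feedback intensities |

The constraints, in order of precedence:

1. `(eta_1 + delta_1) / omega_CSC = 0.025`, so that the baseline invasion
   boundary sits at `P* = 0.025` exactly.
2. The initial tumor (`cscInitialState()`) has 1e5 cells — the order of
   magnitude of a subcutaneous injection — with terminal cells the
   largest compartment (85 000) and CSCs the smallest (100).
3. Under the standard study conditions (uniform ±50% variation of every
   rate, `P_sy` over its full range, T = [0, 200] days), the ensemble
   reproduces the characteristic switching pattern: the lowest `P_sy`
   color level is dominated by unsustainable growth, the second level
   mixes both outcomes, and the top two levels grow in every sample.

Constraint 3 fixes the two parameters the first two constraints leave
free. The feedback intensity `h = 1.5e-4`/cells makes the initial
terminal-cell stock depress proliferation by a factor of about 13.75, so
that intermediate `P_sy` values are initially below their *effective*
(feedback-inflated) invasion threshold; the TC death rate
`delta_3 = 0.01`/day sets how quickly that suppression releases. Together
they place the boundary of finite-horizon extinction inside the second
`P_sy` level: weaker feedback confines extinction to `P_sy < 0.075` (the
widest asymptotic threshold under ±50% variation) and empties the second
level; stronger feedback or slower TC clearance pushes extinctions into
the upper levels, which the switching pattern forbids. The calibration
was done by scanning these two values against constraint 3 at n = 200
and was not revisited afterwards.

**Extinction band.** A sample counts as unsustainable when its final CSC
count lies below the shared initial value (100 cells): over a 200-day
horizon a CSC pool that has not grown has failed to establish the tumor.
This relative band, rather than literal extinction (< 1 cell), matches
how the log-scale trace figures read: declining traces are classified as
non-growing even when the decay has not yet reached zero.

# Latin hypercube sampling

Each parameter's range is resolved from a baseline and a variation
percentage (`±v%`) or explicit bounds (`P_sy` uses [0, 1]). The range is
divided into n equal-probability strata, each sampled exactly once,
uniformly within the stratum; normal distributions use equal probability
mass via the inverse CDF and are left untruncated unless explicit bounds
are given. Columns are permuted independently.

Two design decisions are worth noting:

* **Per-column substreams.** Each column's RNG stream is seeded by a hash
  of (master seed, parameter name). Adding or reordering parameters
  therefore never perturbs the draws of other columns, which keeps
  regression tests meaningful as a study grows.
* **Clipping.** A large `var_pct` on a small baseline can produce a
  negative lower bound; for parameters flagged non-negative the bound is
  clipped to 0 with a message. Whether re-sampling or clipping is the
  "right" treatment is undecidable from first principles; clipping is
  transparent and preserves stratification on the clipped range.

# Ensemble simulation

Each design row is integrated with a stiff-capable implicit-switching
solver (`deSolve`'s `lsoda`, with the model's analytic Jacobian when
available) at `rtol = 1e-8`, `atol = 1e-10`. Failures are data, not
crashes: a row that diverges or stalls is flagged, logged and excluded
listwise from statistics, and only a failure rate above 50% aborts the
run. Trajectories of the CSC model remain non-negative to within solver
tolerance for non-negative initial states (tested property), so no
clipping is applied to the solutions.

# Time-course PRCC

For parameter j at time t and output v, all design columns and the
output slice are rank-transformed (ties averaged); the ranks of column j
and of the output are each residualized by least squares on the ranks of
the other k − 1 columns plus an intercept, and PRCC is the Pearson
correlation of the residuals. Significance uses
`t = PRCC * sqrt((n - 2 - p) / (1 - PRCC^2))` with `p = k - 1`, two-sided
against Student-t with `n - 2 - p` degrees of freedom; the critical
magnitude `r_crit = t_crit / sqrt(t_crit^2 + df)` bounds the shaded
non-significant band in the plots. The default `alpha = 0.01` follows
the convention of reporting raw p-values; a Bonferroni option across
parameters is available but off by default.

Because the design ranks do not change over the time course, the
residualizing QR decompositions are factored once per ensemble and
reused at every time point — the residual-regression estimator is
unchanged, only refactored. Its equality with a matrix-inversion
partial-correlation oracle (and with the per-slice computation) is
asserted in the tests to 1e-10.

Two degenerate cases are handled explicitly: an output that is constant
across samples at some time (always the case at t = 0 with a shared
initial state) yields NA coefficients at that time with no error, and a
constant design column is rejected.

**A structural caveat on early times.** With a shared initial state, all
output variation at t → 0+ vanishes, and for downstream compartments the
first portion of the course is dominated by the decay of the initial
terminal-cell stock (rate `delta_3`) rather than by the lineage
parameters. `P_sy` dominance over every variable is therefore asserted on
the plateau phase (t ≥ 120 here) where the ensemble has forgotten the
initial condition, and over the full course (t > 0) for `N_CSC`, which
responds to `P_sy` directly. This is a property of any shared-initial-
state design, not of a particular baseline choice.

# Level partitions and colored figures

A key parameter's range is split into r equal-width levels; r = 4 with
the black/blue/red/green order is the default, other r get a generated
palette. The first interval is closed on both ends, the rest are
left-open right-closed. Legends print bounds rounded half-up to two
decimals while internal boundaries keep full precision — published
versions of such tables are not always consistent between truncation and
rounding, so the package keeps one rule and documents it. Derived
combinations (`combineColumns()`, grammar restricted to +, −, * and
parentheses over design columns) are usable anywhere a parameter column
is. On log scale, values ≤ 0 are clipped to a configurable floor
(default 1e-3 cells) and the clipped count is recorded in the figure's
JSON sidecar along with the partition bounds and per-level counts, so
figures are machine-checkable without image parsing.

# Bifurcation scan

`scanParameter()` uses grid continuation rather than pseudo-arclength:
for a one-parameter, transcritical-only use case a scan with bisection
refinement is sufficient and much easier to verify. At each grid value
the trivial equilibrium is polished by damped Newton (with a
Levenberg–Marquardt fallback for singular Jacobians) and classified by
Jacobian eigenvalues; `tol_stab = 1e-9` separates stable from marginal,
and marginal points are labeled rather than forced into either class.
The nontrivial branch is seeded by simulating to `10 / min(death rate)`
and polishing; because the positive attractor typically exists on only
one side of the crossing, the seed simulation is attempted at both ends
of the scan and continuation proceeds from whichever end yields a
nonzero attractor (additional seeds can be supplied to track interior
unstable branches, as in the bistable fixture's middle branch). Sign
changes of the trivial branch's leading eigenvalue are refined by
bisection to 1e-6 in the parameter. Every reported equilibrium is
re-checked against `‖rhs‖` independently of the root-finder in the test
suite.

# What the fixtures do and do not show

The three fixture models (`logistic`, `monotone_linear`, `bistable_toy`)
validate the machinery on systems with closed-form answers: integration
accuracy against the logistic solution, rank statistics against a static
monotone response (embedded as a relaxation ODE so the whole time-course
path is exercised), and branch/stability bookkeeping against a cubic
with known equilibria. Passing them shows the workflow's plumbing is
correct; it does not validate the CSC model against biological data, and
the synthetic ensembles inherit every simplification of the model
(deterministic dynamics, well-mixed compartments, no treatment, no
spatial structure, a single feedback mechanism).

# Problem sizes and reproducibility

The shipped configurations use n = 1000 samples, 200 time points over
[0, 200] days and r = 4 levels for the population study; the test suite
exercises the same pipelines at n = 200–1000 and completes in about half
a minute on one core, with 21-point bifurcation grids refined by
bisection. All randomness flows from explicit integer seeds (configs
reject a missing seed), and identical seeds reproduce designs
bit-for-bit; ensembles are deterministic given a design, solver and
platform.

# Known limitations

* The closed-form invasion boundary is exact only without
  de-differentiation; the package flags, rather than resolves, the
  `gamma_PC > 0` case.
* The bifurcation module detects transcritical crossings only; Hopf
  bifurcations, limit cycles and codimension-2 phenomena are out of
  scope, as are correlated sampling designs and variance-based (Sobol)
  indices.
* Adaptive (variable-r) partitioning is not implemented; r is uniform
  over the range.
* PRCC measures monotone association; non-monotone dependence (e.g. the
  bistable fixture's interior branch) can yield small coefficients
  despite strong influence, which is why the colored visualizations
  accompany the statistics.
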