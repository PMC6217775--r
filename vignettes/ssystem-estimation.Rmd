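---
title: "Estimating S-system parameters with decomposition particle swarm optimization"
author: "ssfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating S-system parameters with decomposition PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfit)
```

## The model class

An S-system describes a biochemical network of $N$ dependent metabolite
concentrations $x_1,\dots,x_N$ (plus $m$ constant independent inputs
$x_{N+1},\dots,x_{N+m}$) by pairing, for every state, a power-law production
term with a power-law degradation term:

$$\dot x_i \;=\; \alpha_i \prod_{j=1}^{N+m} x_j^{g_{ij}}
  \;-\; \beta_i \prod_{j=1}^{N+m} x_j^{h_{ij}},
  \qquad i = 1,\dots,N .$$

The rate coefficients $\alpha_i, \beta_i \ge 0$ set the time scales; the
kinetic orders $g_{ij}, h_{ij}$ are real exponents (negative = inhibition,
zero = no interaction). A zero rate coefficient encodes a structurally
absent term. The *structure mask* — which entries are free — is assumed
known throughout; only the numeric values are estimated, from a sampled
multivariate time course.

Estimation is hard because the map from parameters to trajectories is
strongly nonlinear and the objective surface is multimodal with long curved
valleys: within one equation, a production rate and the matching
self-degradation order can trade off against each other with almost no
change in the fitted trajectory over a finite window. This shapes everything
below.

## Objective

A candidate parameter vector is decoded into the model template, the ODEs
are integrated from the first observed sample, and the discrepancy to the
data is pooled over all states and times:

$$\mathrm{RMSE}_{\mathrm{norm}} =
  \sqrt{\tfrac{1}{nN}\sum_{k=1}^{n}\sum_{i=1}^{N}
  \bigl(y_i[k]-\hat y_i[k]\bigr)^2 } .$$

Both this normalized form and the plain summed form
($\mathrm{RMSE}_{\mathrm{sum}} = \mathrm{RMSE}_{\mathrm{norm}}\sqrt{nN}$)
are available; the normalized one is the default and the reporting metric,
because its magnitude is comparable across grids and state counts. The two
differ only by a monotone factor, so rank-based optimizers behave
identically under either. A candidate whose simulation fails — step-size
collapse or numeric blow-up, which is routine for bad parameter regions —
scores a fixed penalty of $10^6$, large enough to dominate any genuine
RMSE without overflowing swarm arithmetic. The initial state is taken from
the data and is not estimated.

## Numerical choices

*Integration.* Trajectories are integrated with an adaptive embedded
Cash–Karp Runge–Kutta 4(5) scheme (default `rtol = 1e-6`, `atol = 1e-8`),
implemented in compiled code because a single benchmark fit evaluates the
objective tens of thousands of times. States are clipped to a floor of
$10^{-9}$ *inside rate evaluation only*, so fractional and negative kinetic
orders remain defined if a trajectory touches zero during exploration; the
integrator state itself is not altered. The test suite checks this
integrator against closed-form solutions, an independent fixed-step RK4
oracle, and `deSolve::lsoda`.

*Search tolerances.* During optimization the objective uses
`rtol = 1e-4`, `atol = 1e-6` and a cap of 150 internal steps per output
interval. This bounds the cost of near-stiff candidates and leaves an
integration-error floor on the objective of order $10^{-3}$ — two orders of
magnitude below the RMSE differences the comparison measures. Final
estimates are re-scored at the tight tolerances.

*Encoding.* Free parameters are flattened in a fixed order — free
$\alpha$, free $\beta$, free $G$ row by row, free $H$ row by row — which
makes the encode/decode pair a bijection on the free subspace and fixes the
meaning of every optimizer dimension.

## The estimators

All four estimators minimize the same objective inside the same box:
rates in $[0, 25]$, kinetic orders in $[-2, 2]$ — chosen to enclose the
benchmark truth with a wide margin while excluding absurd regimes.

**PSO.** Canonical particle swarm with inertia-weighted velocity updates,
$c_1 = c_2 = 2$, and an inertia weight decaying linearly from 0.9 to 0.1
over the run, shifting the swarm from exploration to exploitation.
Velocities are clamped per dimension to a fraction of the box width.
Two details matter on this landscape and apply to *both* swarm algorithms
symmetrically:

- a tight velocity clamp (5% of box width in the benchmark harness,
  rather than the 20% textbook value) — with ~83% of the box scoring the
  failure penalty, large velocities fling particles onto the flat penalty
  plateau where the swarm learns nothing;
- feasibility-screened initialization: initial particles whose simulation
  fails are redrawn (up to 25 rounds), so the starting swarm carries
  information. The redraws are counted toward the evaluation budget. This
  is unbiased within the feasible region — no knowledge of the truth is
  used.

**DPSO.** Two phases. Phase 1 is the canonical PSO above. Phase 2 applies
coordinate-wise decomposition: repeatedly, for each dimension $j$, all
particles are relocated to the incumbent global best, scattered only along
dimension $j$ (within 5% of the box width), and a one-dimensional PSO is
run with every other coordinate frozen; the incumbent is replaced only on
strict improvement. On a landscape of correlated valleys single-coordinate
moves near a good solution are deliberately *small* — that is the point of
the exploitation phase. Benchmark pilots showed that the decomposition adds
the most value as a short terminal refinement of a long, well-annealed
phase 1 (the swarm's linearly decaying inertia is tied to its iteration
count, so phase-1 length buys global search quality that sweeps cannot
replace); the default sizing therefore gives phase 1 about 80% of the
budget and closes with six sweeps of $7\times14$ single-dimension
searches. Phase-2 velocities are re-initialized to zero on relocation.

**SA.** Single-solution simulated annealing: Gaussian proposals (SD 10% of
box width per dimension) clamped to the box, Metropolis acceptance
$\min\{1, e^{-\Delta/T}\}$, geometric cooling with ratio 0.95. When no
initial temperature is given it is calibrated as the standard deviation of
50 random fitness probes (drawn uniformly in the box and counted toward
the budget), and the final temperature is $10^{-3}$ of the initial one —
roughly 135 temperature levels.

**UKF / IUKF.** The parameter vector is treated as the state of a random
walk observed through one-step-ahead predictions: from each measured sample
$x[k]$, the model integrates one interval to predict $x[k+1]$. A scaled
unscented transform propagates $2q{+}1$ sigma points through this map. The
iterated variant repeats full-data passes, each initialized from the last
pass's estimate and covariance; it stops early when the trajectory RMSE of
the running estimate falls below $\delta_E = 10^{-3}$, resets the
covariance to its initial value when consecutive pass RMSEs differ by less
than $\delta_R = 10^{-4}$ (reopening a saturated gain), and restarts from a
fresh prior draw when a pass diverges. The best estimate across passes is
returned.

Two UKF constants deviate from the obvious defaults for cause:

- *Sigma spread* $\varepsilon$: the admissible range is $(10^{-4}, 1)$,
  but with $q = 17$ a small $\varepsilon$ makes the centre covariance
  weight $W_0 = \lambda/(\lambda+q)$ hugely negative (about $-10^4$ at
  $\varepsilon = 10^{-2}$), which reliably drives the innovation covariance
  indefinite in finite precision. The default here is $\varepsilon = 0.5$,
  where $W_0 = -3$ and the filter is numerically stable.
- The covariance downdate can still leave a slightly indefinite matrix;
  its spectrum is clamped at zero after every update, and the matrix square
  root in the sigma-point construction is the symmetric eigendecomposition
  root with a $10^{-10}$ jitter on near-singular spectra.

Sigma points whose one-interval integration fails predict "no change"
(the current sample), a neutral value that keeps the update defined.

## The synthetic benchmark

The generator emulates a four-metabolite cascade with one constant input
fixed at 1: production of $x_1$ is inhibited by $x_3$
($g_{13} = -0.8$), $x_2$ and $x_4$ are driven by $x_1$, $x_3$ by
$x_2$, and every state degrades as a power of itself ($x_3$'s degradation
also involves $x_4$). True values: $\alpha = (20, 8, 3, 2)$,
$\beta = (10, 3, 3, 6)$, orders
$g_{21} = g_{41} = 0.5$, $g_{32} = 0.75$,
$h_{11} = h_{33} = 0.5$, $h_{22} = 0.75$, $h_{34} = 0.2$,
$h_{44} = 0.8$. The input's kinetic order on $x_1$ is fixed at zero and
excluded from estimation, leaving 17 free parameters.

Each replicate draws a fresh initial state uniformly from $[0.1, 1]^4$
and samples the exact trajectory at 50 equispaced times on $[0, 5]$ — a
window in which all four states complete their initial transient and
approach steady state, so the data constrain both kinetics and
equilibria. The noisy scenario adds zero-mean white Gaussian noise per
state column at 20 dB signal-to-noise (noise variance = column mean-square
signal / $10^{20/10}$); decibels are the standard convention for
signal-to-noise ratios, and 20 dB corrupts the profiles visibly but
mildly. Replicates are seeded deterministically from a single base seed.

What the generator does *not* emulate: measurement grids with missing or
irregular samples, state-dependent or multiplicative noise, model
misspecification (the fitted structure is exactly the generating
structure), and unobserved states. Passing benchmarks here therefore
demonstrates optimizer behaviour under ideal observability, not robustness
to real experimental artifacts.

## The comparison harness

One experiment fixes a scenario (noise-free or 20 dB), draws 20
replicates, and runs the selected algorithms on identical data per
replicate. PSO, DPSO and SA consume equal fitness-evaluation budgets
(PSO via its iteration count, SA via its per-temperature move count and an
exact evaluation cap); the default sizing is DPSO = $40\times1000$ phase-1
evaluations plus $6 \times 17 \times (7 \times 14)$ phase-2 evaluations,
about 50&nbsp;750 in total. The IUKF's cost unit is filter passes, not
fitness evaluations, so it is capped at 50 passes instead of being
budget-equalized. PSO and DPSO share each replicate's seed, making the
DPSO-vs-PSO comparison a paired design. Estimates are always *fitted* to
the observed (possibly noisy) data and *scored* against the noise-free
truth, which is available because the data are synthetic.

Reported per algorithm: per-replicate and mean normalized RMSE, the mean
decoded parameter estimates in the standard table layout, and the
percentage RMSE improvement of DPSO over each comparator,
$100\,(\mathrm{RMSE}_{\mathrm{base}} -
\mathrm{RMSE}_{\mathrm{DPSO}})/\mathrm{RMSE}_{\mathrm{base}}$.

The replicate count (20) and the budget (~51k evaluations) are desk-scale
choices: they keep a full two-scenario comparison within minutes on one
core while leaving the ranking of the four estimators stable across base
seeds. Larger replicate counts sharpen the means without changing the
qualitative picture.

## Known limitations

- Coordinate-wise decomposition cannot improve on a point whose
  one-dimensional conditional minima all coincide with the point itself;
  in the correlated valleys of S-system objectives this limits how much
  phase 2 can add to a well-converged phase 1, and run-to-run basin
  variability of the swarm phase remains the dominant source of spread in
  paired comparisons.
- Identifiability: distinct parameter vectors can fit one finite window
  almost equally well, so a small trajectory RMSE does not imply small
  parameter error; parameter-recovery summaries average over replicates
  for that reason.
- The UKF treats states as fully observed; joint state-parameter
  augmentation (needed for partially observed systems) is out of scope.
- Independent inputs are constant over a simulation; time-varying inputs
  are not supported.

## A minimal session

```{r example, eval = FALSE}
library(ssfit)

# the benchmark model and one noisy data set
model <- benchmark_model()
mask  <- benchmark_mask()
x0    <- sample_initial_state(initial_state_sampler(seed = 7))
truth <- ss_simulate(model, x0, seq(0, 5, length.out = 50), inputs = 1)
data  <- add_noise(truth, snr_db = 20, seed = 8)

# fit with DPSO
ctx <- fitness_context(data, model, mask, x0 = x0, inputs = 1,
                       rtol = 1e-4, atol = 1e-6, max_steps = 300)
f   <- ss_fitness(ctx)
b   <- param_bounds(mask)
cfg <- dpso_config(pso_config(40, 600, b, vmax_frac = 0.05,
                              feasible_init = TRUE, seed = 1),
                   outer_iterations = 8,
                   inner = pso_config(6, 13, b))
res <- run_dpso(cfg, f)
fitted <- ss_decode(res$best_vector, mask, model)

# replicated four-algorithm comparison (several minutes)
rep <- run_experiment(experiment_config("noisefree", base_seed = 1))
print(rep)
```
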