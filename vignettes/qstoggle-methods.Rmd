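---
title: "Methods: models, monotonicity, and numerics in qstoggle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, monotonicity, and numerics in qstoggle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstoggle)
```

## The system

A genetic toggle switch is a pair of mutually repressing genes — here *lacI*
(product LacI, level $x$) and *tetR* (TetR, level $y$) — forming a bistable
memory element: either LacI is abundant and TetR scarce (the "green" G state)
or the reverse (the "red" R state). In a population, molecular noise
occasionally flips individual cells, producing mixed populations and bimodal
expression — *spontaneous synchronization errors*. Quorum sensing (QS) lets
cells broadcast their state: intracellular autoinducers (C14-HSL, level $g$;
C4-HSL, level $r$) are exported to a shared medium ($g_e$, $r_e$) and feed
back as transcriptional activators, so the medium acts as a majority vote.

`qstoggle` implements two architectures:

* the **S design** — each repressor has its own QS arm ($g$ activates $x$,
  $r$ activates $y$), wired so the circuit is *mirror-symmetric* under the
  involution $\sigma$: $x \leftrightarrow y$, $g \leftrightarrow r$,
  $g_e \leftrightarrow r_e$ (and the paired parameters);
* the **A design** — the classical single-arm benchmark: only one
  autoinducer, activating $x$, with no green arm.

For $N$ cells the S model has $4N + 2$ state variables and the A model
$3N + 1$; all cells share the extracellular pool, coupled through the
mean-field term $(\rho/N)\sum_i d\,(g_i - g_e)$, where $d$ is the
dimensionless diffusion (membrane permeability) coefficient and $\rho$ the
population density. Regulation is by Hill functions
$u^n/(1+u^n)$ (activation) and $1/(1+u^n)$ (repression); see `?toggle_rhs`
for the full equations.

## Parameters

The `"reference"` preset is the working point of all analyses: zero
leakiness, $a_1 = a_2 = 20$, $a_3 = a_4 = 10$, $a_5 = a_6 = 3$, Hill
coefficients all $3$, $\delta_g = \delta_r = 1$, $\delta_e = 0.5$,
$\rho = 0.8$. Time is dimensionless, scaled by the repressor decay rate
$r_d + \mu$, so repressor time constants are $1$; `nondimensionalize()`
maps a dimensional rate set onto this scale. The `"modified"` preset
(leakiness $0.01$, $a_1 = a_2 = 100$, $n_X = n_Y = 2$, $n_G = 1$,
$n_R = 2$) deliberately breaks the mirror symmetry ($n_G \neq n_R$) and is
used to probe robustness of every symmetric-case conclusion.

Two choices the presets make that the published set leaves open:

* **`d` default.** The diffusion coefficient is the standing bifurcation
  parameter and has no published reference value; presets carry the
  weak-coupling value `d = 0.1`, which is the base point of all mixed-state
  continuations here.
* **Hill exponents** are accepted as any real $\ge 1$ (values used in
  practice are 1, 2, 3); states are clamped to $u \ge 0$ before
  exponentiation so transient solver overshoots cannot generate NaNs.

## Monotonicity machinery

The signed species-influence graph (`influence_graph()`) has one node per
state variable and an edge $j \to i$ with the global sign of
$\partial f_i/\partial z_j$; self-edges are excluded, and an edge is dropped
when the rate it rides on is zero. Signs are declared from the closed-form
Jacobian and *validated* by sampling the Jacobian at 100 random positive
states (log-uniform in $[10^{-3}, 10^2]$); any sampled sign flip is an
error, because the whole framework assumes globally sign-constant
interactions.

Orthant monotonicity is equivalent to balance of this signed graph:
2-colourability with + edges joining like colours and − edges unlike
colours. `find_orthant_partition()` decides it by BFS sign propagation and,
on failure, returns a closed walk with an odd number of negative edges as a
witness; a brute-force search over all colourings backs it in the tests at
small size. For the S design the split is $\{x_i, g_i, g_e\}$ versus
$\{y_i, r_i, r_e\}$ for every $N$; the A design's two oppositely-signed
$x$–$r$ interactions give an odd cycle, so no orthant order exists. Strong
connectivity (via `igraph`) upgrades monotone to *strongly monotone*, which
is what guarantees generic convergence to equilibria.

The order used everywhere is oriented "larger = greener": $\ge$ on the
green set, $\le$ on the red set. `kamke_order_check()` verifies order
preservation by integrating the two ordered initial conditions as one
coupled $2n$-dimensional system, so both trajectories share one adaptive
step sequence and discretization errors largely cancel in the comparison;
the order is then asserted with absolute tolerance $10^{-9}$ (strict
inequalities degrade to weak ones under floating point). The eight
parameters $a_1 \dots a_6, \delta_g, \delta_r$ embed as constant states
with a definite partition side, which predicts the direction of every
stable equilibrium's shift under a parameter change
(`parametric_monotonicity_check()`); the diffusion coefficient `d` admits
no such embedding and no ordering in `d` is ever asserted.

## Equilibria and spectra

`find_equilibrium()` is a damped Newton iteration (Armijo line search) on
the analytic Jacobian with residual tolerance $10^{-10}$ and at most 200
iterations; results are projected onto the non-negative orthant and
classified through the Jacobian spectrum with a *stability margin* of
$10^{-7}$: leading real parts within $\pm 10^{-7}$ are reported "marginal"
rather than silently stable or unstable, which separates genuine
bifurcation-point marginality from round-off. Equilibria found by
multistart (`enumerate_equilibria()`) are deduplicated at relative
sup-norm distance $10^{-6}$, since Newton basins overlap.

For a single toggle decoupled from the medium ($d = 0$) the equilibrium
problem reduces exactly to one scalar equation (the autoinducers are
explicit functions of the repressors), which `single_toggle_equilibria()`
solves by sign-change bracketing on a 400-point grid plus bisection. The
bistability scans over the $(a_1, a_2)$ plane run on this reduction — the
grid is $[0, 50]^2$ with step 1, covering the reference point $(20, 20)$ —
and the tests cross-check it against the multistart Newton route at spot
points. The reduced "S$_R$" design is simply the reference preset with
$a_1 = a_2 = 0$, not a separate model.

One modelling choice in the leakiness sweep of these scans deserves
spelling out. A single "leakiness" dial $\gamma$ fans out into several
independent leak terms ($\gamma_x, \gamma_y, \gamma_g, \gamma_r$), and the
designs resolve it differently. For the **S** scan, $\gamma$ is applied to
the repressor-gene equations only ($\gamma_x = \gamma_y = \gamma$,
autoinducer leaks zero): the whole quadrant then stays bistable up to
$\gamma = 1$. Applying $\gamma = 1$ to the autoinducer equations as well
is a *different* experiment — a constitutive autoinducer supply of a third
of $a_5$ — and verifiably destroys bistability (both solution routes find
a single symmetric state $x = y \approx 6.18$); it is not what the
whole-quadrant robustness claim is about. For the **A** scan, $\gamma$ is
applied to all three leak terms, which is forced by the circuit itself:
one promoter (P$_X$) drives both *tetR* and *rhlI*, so its leak feeds
$\gamma_y$ and $\gamma_r$ alike. Under that reading the A design's
bistable region shrinks with $\gamma$ and leaves the sampled grid just
above $\gamma = 0.5$ (fraction still bistable: 0.9% at 0.50, 0.1% at
0.55, none at 0.60).

Stability of population equilibria is $N$-independent in the following
sense: the Jacobian consists of identical per-cell blocks within each
subpopulation, a rank-one mean-field row of weight $\rho d/N$ per cell, and
a uniform column $d$ back from the medium. Its eigenvalues split into
symmetry classes — a *synchronous* class governed by one representative
cell per subpopulation with coupling weight $\rho p_k d$ ($p_k$ the
subpopulation fraction), and *anti-synchronous* classes equal to the bare
cell blocks with multiplicity $N_k - 1$. The distinct eigenvalues therefore
coincide with those of auxiliary systems of 2 (homogeneous), 3 ((1:1),
where the mirror pairs the two anti-synchronous blocks) or 4 (general
$(N_1\!:\!N_2)$) toggles. `reduced_spectrum_check()` builds this
construction from the eigenvector symmetry classes — numerically robust and
exactly equivalent to the Schur-complement factorization of the
characteristic polynomial for this block structure — and verifies the
coincidence against a full eigensolve at tolerance $10^{-6}$; the
equivalence is always asserted, never assumed.

## Continuation

`continue_equilibrium()` is secant-predictor / Newton-corrector
pseudo-arclength continuation. Step control: initial arclength step 0.01 in
$[10^{-5}, 0.1]$, halved on corrector failure, grown by 1.3 after four
consecutive successes — tight enough to resolve events to two decimals.
Two test functions are monitored between accepted points:

* **LP (fold):** sign change of the parameter component of the unit
  tangent, with the bordered determinant keeping its sign;
* **BP (branch point / pitchfork):** sign change of the determinant of the
  bordered square matrix $[J\; f_p;\; t^\top]$, which is singular at a
  transversal crossing but regular at a fold.

This pair distinguishes folds from symmetry-breaking crossings without any
normal-form computation. Events are localized by bisection along corrected
points to parameter tolerance $10^{-4}$. `branch_switch()` perturbs along
the critical eigenvector in both orientations just past a BP and corrects
at fixed parameter, rejecting candidates that fall back onto the original
branch; for mirror-symmetric parameters the two switched branches are
$\sigma$-images of each other.

The (1:1) continuations use the minimal representative population — one
cell per subpopulation — justified by the spectrum reductions above (and
re-asserted by `reduced_spectrum_check`, not assumed). At the reference
set this locates the symmetry-breaking branch point of the symmetric mixed
state near $d \approx 1.42$ and the fold terminating the asymmetric branch
near $d \approx 2.07$; the (9:1) error state is eliminated through a fold
already near $d \approx 0.85$, while the A design's mixed states persist
stably to $d = 100$ — the design contrast at the heart of the analysis.

## Time integration

No stiff implicit integrator is bundled; instead `integrate_toggles()` is
an embedded Dormand–Prince 5(4) pair with PI step control at
`rtol = 1e-8`, `atol = 1e-10`. This is a deliberate choice: the fastest
rate in the Jacobian is about $d + \delta$, at most $\approx 110$ in any
run here, so the explicit stability restriction is mild at desk scale,
while a 5th-order pair reaches the tight tolerance far more cheaply in
interpreted R than an implicit method paying a dense LU per step. Two
consequences are handled explicitly:

* the early-stop criterion ("at an equilibrium") scales its vector-field
  threshold with $\max(1, d)$, because $\|f\|$ near an equilibrium is the
  state error amplified by the fastest rate;
* convergence of an experiment trajectory is certified not by the raw
  terminal residual but by a terminal *Newton polish*: the end state must
  lie in the Newton basin of a stable equilibrium within
  $10^{-3}(1 + \|z^*\|_\infty)$. Samples failing this are reported
  "undecided", never "corrected".

## The synthetic-data generator

The experiments consume no external data; `generate_initial_conditions()`
is the data stand-in. It emulates the two situations the self-correction
protocol requires: (a) neighborhoods of equilibria — every component is
multiplied by $e^\varepsilon$, $\varepsilon \sim N(0, \text{noise}^2)$ —
and (b) flipped populations, where a fraction of cells is replaced by the
opposite homogeneous state's per-cell block before the noise is applied.
Defaults: `flip_fraction = 0.1` (the "flip 10% of the population"
protocol), `noise_scale = 0.05` and `n_samples = 25` — the neighborhood
radius and sample count are unquantified in the source analysis
("small neighborhoods", "simple random tests"), so 5% multiplicative noise
and 25 samples per condition are this package's recorded choices, at desk
cost, varied in sensitivity tests. Streams are derived per
`(seed, sample index)`, so a run is bit-for-bit reproducible from one seed.
What the generator does *not* emulate: extrinsic/intrinsic noise during
integration (perturbations are to initial conditions only), low-copy-number
stochasticity, growth-phase dependence of dilution, and reporter-protein
dynamics. A green self-correction test therefore establishes the
deterministic basin structure, not stochastic switching rates.

Correction times are reported in dimensionless units; conversion to
minutes needs the dimensional $r_d + \mu$, and is only meaningful when a
`dimensional_params()` preset supplies it.

## Known limitations

* No two-parameter continuation: the fold loci of the A design's
  bistability region are resolved by grid scan, and the cusp is located
  only to grid resolution.
* No Hopf detection: the theory rules out stable oscillation for the S
  design, and the A design's oscillatory regimes are outside this
  package's parameter sets.
* The ClpXP-sequestration (saturated-protease) model variants are not
  implemented; `toggle_rhs` is written so an alternative degradation term
  can be added, but no functional form is guessed.
* Monotonicity is verified symbolically-numerically (sign sampling plus
  graph balance), not by formal proof machinery, and only for orthant
  orders — not general cones.
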