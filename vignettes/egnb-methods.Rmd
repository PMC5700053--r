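---
title: "Replicator dynamics on brain graphs: model, identification, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics on brain graphs: model, identification, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egnb)
```

## The model

Each brain region $v$ carries an activation level $x_v(t) \in [0, 1]$:
$x_v = 1$ is fully active, $x_v = 0$ fully inactive, and $1 - x_v$ reads as
the inactivation level. Every ordered pair of regions $(v, w)$ plays a
two-strategy game. Region $v$ observes its neighbour's activation $x_w$ and
weighs an activation payoff $\alpha_{v,w}\, x_w$ against an inactivation
payoff $\iota_{v,w}\,(1 - x_w)$; the propensities $\alpha$ and $\iota$ encode
the pair's attitude. Only their difference matters,

$$\Delta p_{v,w} = (\alpha_{v,w} + \iota_{v,w})\, x_w - \iota_{v,w},$$

which changes sign at the activation threshold
$d = \iota / (\alpha + \iota)$ (`activation_threshold()`). Any $2 \times 2$
payoff matrix reduces to an equivalent diagonal game via
$\alpha = b_{11} - b_{21}$, $\iota = b_{22} - b_{12}$
(`reduce_payoff_matrix()`); the package's equivalent-game test verifies that
this reduction leaves the dynamics unchanged.

Aggregating the pairwise games over a weighted directed graph with
non-negative coupling weights $a_{v,w}$ gives the replicator equation on the
graph:

$$\dot x_v = x_v (1 - x_v) \sum_{w=1}^{N} a_{v,w}\, \Delta p_{v,w}.$$

In the *restricted mode* used throughout estimation, each pair's propensities
are equal and carry a single sign, $\alpha_{v,w} = \iota_{v,w} \in \{-1,
+1\}$: positive pairs are emulative (the region copies its neighbour),
negative pairs non-emulative (it opposes it). Weight and attitude then fold
into one *signed connectivity matrix* $A'$ with $a'_{v,w} = a_{v,w}\,
\alpha_{v,w}$, and the drive simplifies to $\sum_w a'_{v,w} (2 x_w - 1)$ —
linear in $A'$, which is what makes the inverse problem convex. A general
mode accepting arbitrary equal-sign propensities per edge is available for
exploratory simulation (`replicator_rhs(..., propensities = )`). Mixed-sign
pairs describe unconditional activation or inactivation — the neighbour's
state never changes the preferred strategy — and are excluded from the
network model.

Three two-region regimes anchor the model's phenomenology and the test
suite: two emulative regions converge to a common activation level; two
non-emulative regions split to opposite boundaries (bistability); a mixed
pair ($a'_{1,2} = +1$, $a'_{2,1} = -1$) oscillates forever around
$(1/2, 1/2)$. The mixed system conserves
$H = -\ln x_1(1-x_1) - \ln x_2(1-x_2)$ (differentiate along the flow: the
two terms cancel exactly), which the suite uses as a demanding integration
accuracy check — the relative drift of $H$ over 100 time units at step 0.01
must stay below $10^{-6}$; the fixed-step fourth-order integrator achieves
$\sim 3 \times 10^{-13}$.

## Numerical integration and the boundary

`simulate_egnb()` integrates with classical RK4 at a fixed internal step
(default one tenth of the output interval), or adaptively (lsoda, tolerances
$10^{-8}$) when `solver_options(method = "adaptive")` is chosen. The RHS is
polynomial, so intermediate RK stages may probe slightly outside $[0,1]$
without harm; only committed output states are corrected.

The boundaries are non-hyperbolic equilibria, which forces an explicit
policy for floating-point behaviour near them:

* `simulate_egnb()` pulls back only components that *escape* $[0,1]$ (to
  $\varepsilon = 10^{-9}$ inside); exact boundary values are genuine fixed
  points and are preserved bit-for-bit, so an all-zero or all-one initial
  state yields an exactly constant trajectory.
* `generate_trajectory()` (synthetic data for estimation) additionally pulls
  *moving* states off the exact boundary: a saturating state can be rounded
  to exactly 0 or 1 in double precision even though the exact map never
  reaches the boundary, and an exact-boundary sample would zero the
  regressor $x(1-x)$ and poison the regression. States whose update is
  exactly zero are true fixed points and stay put, so the two policies
  agree on equilibria.

## Identification

Discretizing the restricted-mode equation by forward Euler at the sampling
interval $\Delta t$ gives, per node $v$ and sample $k$,

$$\frac{x_v[k+1] - x_v[k]}{\Delta t}
  = x_v[k]\,(1 - x_v[k]) \sum_w \theta_{v,w}\,\bigl(2 x_w[k] - 1\bigr),$$

linear in $\theta = \mathrm{vec}(A')$. The stacked system $Y = U\theta$ is
exactly block-diagonal — node $v$'s rows involve only row $v$ of $A'$ — so
`estimate_connectivity()` solves the $N$ decoupled least squares problems
(QR for ridge 0, regularised normal equations otherwise); a test confirms
the per-block solution equals the stacked solve, and an independent
conjugate-gradient minimiser of $F(\theta) = \lVert Y - U\theta\rVert$
agrees with the closed form to $10^{-10}$. Forward Euler was chosen because
it is the simplest scheme preserving linearity in $\theta$; a central
difference variant (`scheme = "central"`) is available and decorrelates the
regressor's observation noise from the response's, at the cost of one
sample and of the exact noiseless round trip. Since the generator's Euler
scheme and the estimator share the same discretization, noiseless synthetic
recovery is exact up to conditioning — the end-to-end pipeline recovers a
10-node modular truth to $\sim 10^{-8}$ max absolute error.

Raw BOLD signals live in scanner units; `scale_bold()` maps each node
affinely onto $[\delta, 1-\delta]$ (default $\delta = 0.05$) so that every
sample keeps $x(1-x)$ bounded away from zero, and returns the inverse map.
`dt` defaults to the repetition time supplied by the user; estimates scale
as $1/\Delta t$, so the sign structure is $\Delta t$-invariant.

**Ridge and identifiability.** The package default is ridge 0 — the faithful
closed-form solution. Two failure modes call for regularisation, and the
estimator's error message says so. First, regions that synchronise within
the observation window become numerically indistinguishable *sources*: their
regressor columns are collinear and the design loses rank (dense 10-node
clusters reliably trigger this; the estimator refuses rather than return an
arbitrary split). Second, with observation noise the split of a synchronised
group's joint influence across its members is ill-determined even at full
numerical rank; plain least squares then assigns near-arbitrary signs within
the group. A modest ridge (0.3 in the validation studies) shrinks the split
toward the group's well-determined collective mean, whose sign is correct —
sign agreement on a noisy ($\sigma = 0.01$) 10-node modular truth rises from
roughly 60–85% to above 98%. The ridge is deliberately *not* part of the
noiseless studies, which demonstrate the exact closed form.

## Prediction and the linear baseline

`predict_egnb()` estimates $A'$ on the first `n_train` samples (default 90,
a typical resting-state training window) and iterates the model forward from
the last training state. The default forward map is the same Euler
discretization used by the estimator, so noiseless round trips are exact; a
continuous-time forward run is available (`simulator = "ode"`). Errors are
the mean over nodes of the absolute deviation at each held-out step, with an
RMSE alongside — the error unit is activation level, i.e. a fraction of each
node's dynamic range.

The comparator (`fit_linear_baseline()`) is a discrete affine AR(1) system
$x[k+1] = M x[k] + c$, fit by least squares on the training window and
iterated over the held-out window with the *identical* error functional
(asserted by a test that rescoring both models' predicted series with one
shared formula reproduces their reports). The fit is parameterised on the
one-step change, so ridge shrinks $M$ toward the identity (a random walk)
rather than toward zero. Out-of-range linear iterates are clamped to valid
activations before scoring, which only ever helps the baseline. Where the
oscillation is small the replicator dynamics are well approximated by their
linearisation and the baseline is genuinely competitive; the model
comparison study therefore uses the strongly nonlinear regime — a mixed
two-region oscillator started near the boundary ($x_0 = (0.1, 0.5)$) —
where the replicator model's held-out error is several-fold smaller.

## Synthetic data: what it emulates and what it does not

`synthetic_spec()` describes the study conditions: modular networks with
emulative (positive) couplings inside clusters and non-emulative (negative)
couplings between them, echoing within-network synchrony and
between-network anti-correlation of resting-state recordings, plus
measurement noise added to the states after integration (no process noise)
and an fMRI-like sampling regime — one sample every 3 s, 180 samples
(9 minutes). Only the product $\Delta t \cdot a'$ enters the discrete
dynamics (time-rescaling invariance), so coupling magnitudes and sampling
interval trade off exactly; defaults pair weights $[0.02, 0.08]$ with
$\Delta t = 3$ s so per-step updates stay at a few percent of the range.
Validation studies that fix unit-scale weights $[0.5, 1.5]$ accordingly use
a proportionally finer $\Delta t$ (0.005–0.05): these values were chosen
once from the stability requirement $\Delta t \cdot \sum_w |a'_{v,w}| < 1$
and from requiring the observation window to cover the informative
transient, and then frozen.

A structural property of the pure modular motif worth knowing: it is
*bistable*. One cluster captures the high boundary, the other the low one,
and after a transient of a few coupling time-constants the trajectory
saturates. Synthetic series from this motif therefore carry their
information in the transient — unlike real BOLD, which fluctuates for the
whole acquisition. Consequences, all visible in the test suite: long
noiseless series remain exactly recoverable (the saturated samples are
consistent with the model), but under noise the saturated stretch
contributes errors-in-variables rows and no signal, and estimation error
*grows* with record length on this motif. The monotone
error-versus-record-length study therefore uses the sustained mixed-attitude
oscillator (integrated with RK4, since the Euler map slowly spirals outward
and eventually saturates), where longer records are genuinely more
informative. Dense clusters of 10+ nodes synchronise tightly enough to lose
numerical rank even without noise; the estimator reports this rather than
guessing. Synthetic trajectories are model states plus i.i.d. Gaussian
noise — no haemodynamic response function, drift, or physiological noise —
so passing tests demonstrate correctness of the machinery on model-generated
data, not performance on real BOLD.

## Lesioning

`lesion_response()` implements the four-step in-silico protocol: simulate
the intact network, delete the target's row and column from $A'$
(`lesion_node()`), re-simulate the survivors over a grid of the same length
from the intact initial condition restricted to the survivors (the lesioned
initial state is otherwise unconstrained by the protocol), and compare
survivor functional connectivity (Pearson correlations,
`functional_connectivity()`) before and after. Percent changes are reported
relative to the pre-lesion coefficient and marked undefined (NA) where its
magnitude is below 0.05 — ratios to near-zero baselines would be
meaningless; the absolute difference matrix is always available. Lesion
targets are picked as the node with the highest within-group coupling
strength (`select_lesion_target()`, ties broken by the order labels are
given). Removing a fully disconnected node reproduces the intact survivors
bitwise — adding an exactly zero coupling term does not perturb
floating-point sums — which the suite asserts as a null-lesion control.
In the three-cluster study (15 nodes, hub of cluster 1 removed),
between-cluster correlations shift by tens of percent while the untouched
clusters' internal correlations move by well under 1%, the qualitative
intra-/inter-network rearrangement expected of a hub lesion.

## Problem sizes and determinism

The validation studies use 2–15 node networks, 100–500 samples, and 5–20
Monte-Carlo seeds per stochastic property; each study states its conditions
in the corresponding test. Every random draw flows from an explicit integer
seed through a local RNG scope (`with_seed`), so all generators are
bit-reproducible and never disturb the caller's RNG stream; simulation,
estimation, prediction, and lesion reports are deterministic given their
inputs and options.

## Known limitations

* Estimation assumes the restricted mode; unequal $(\alpha, \iota)$ pairs
  per edge would break linearity in $\theta$ and are not estimable here.
* Errors-in-variables bias: with observation noise the Euler regressors
  contain the same noise as the response; the estimate converges to a
  biased limit as records grow on saturating motifs. The central-difference
  scheme removes the correlation but not the attenuation.
* Networks whose regions synchronise within the window are not fully
  identifiable from a single trajectory — a property of the inverse
  problem, not of the solver.
* No haemodynamic forward model, no multi-node or graded lesions, and no
  group-level inference beyond simple averaging of per-run reports.
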