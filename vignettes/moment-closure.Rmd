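---
title: "Moment closure for globally coupled spiking phase neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment closure for globally coupled spiking phase neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemoments)
```

## The model

`spikemoments` studies a network of $N$ phase neurons coupled through one
shared synaptic drive $u(t)$:

$$
\dot\theta_i = F(\theta_i, \gamma_i, u), \qquad
\dot u = -\beta u + \beta\,\nu(t), \qquad
\nu(t) = \frac1N \sum_{j,l} \delta(t - t_j^l),
$$

where a neuron spikes when its phase crosses $\pi$ (identified with $-\pi$),
each spike kicks $u$ up by exactly $\beta/N$, and the per-neuron coupling
coefficients $\gamma_i$ are drawn i.i.d. from a law $g(\gamma)$. Two velocity
families are supported: the non-leaky integrate-and-fire form
$F = I(t) + \gamma u$ (`linear_phase`), for which all the moment machinery is
derived, and the theta-neuron law
$F = 1 - \cos\theta + (1 + \cos\theta)(I + \gamma u)$, the normal form of a
Type I neuron, available in the simulator and the grid mean-field solver.
Initial phases are i.i.d. from a density $\rho_0$ (uniform, wrapped von Mises
bump, or tabulated), and $u(0) = u_0$ is deterministic.

The package computes the same observables at three levels:

1. **Microscopic** (`simulate_network`): single realizations, exact
   event-driven or dense fixed-step.
2. **Mean field** (`solve_mean_field`, `wilson_cowan_reduced`): the
   $N \to \infty$ density $a_3(\theta, \gamma, t)$ obeying the advection
   (Vlasov) equation
   $\partial_t a_3 + \partial_\theta(F a_3) = 0$ and the mean drive
   $\dot a_1 = -\beta a_1 + \beta \int d\gamma\, F(\pi, \gamma, a_1)\,
   a_3(\pi, \gamma, t)$. For uniform initial phases the density stays
   uniform and the system collapses to the Wilson–Cowan-type rate equation
   $\dot a_1 = -\beta a_1 + \frac{\beta}{2\pi}(I + \bar\gamma a_1)$.
3. **Order-$1/N$ moment closure** (`solve_gae`): closed equations for
   $a_1$, $a_3$, and the equal-time covariances
   $C(\theta,\gamma) = N\operatorname{Cov}(u, \eta(\theta,\gamma))$,
   $C_{11} = N\operatorname{Var}(u)$, and
   $C_{33}(x; x') = N\operatorname{Cov}(\eta(x), \eta(x'))$, where $\eta$ is
   the empirical phase density. The $1/N$ terms feed the covariances back
   into the means, so the closure predicts both the finite-size fluctuations
   and the leading deviation of the ensemble mean from mean field.

A seeded Monte-Carlo ensemble engine (`run_ensemble`) estimates every one of
these quantities empirically and is the ground truth against which the
deterministic solvers are validated.

## Parameters that matter

| Parameter | Meaning | Units | Typical |
|---|---|---|---|
| `N` | neurons; also the expansion parameter | – | 100–800 |
| `beta` | synaptic decay rate of $u$ | 1/time | 1–2 |
| `drive` | external drive $I(t)$, constant or tabulated | rate | 0.5–2 |
| `gamma_law` | law of the coupling coefficient, as nodes + weights | – | point mass 0–1 |
| `rho0` | initial phase density | 1/rad | uniform |
| `u0` | initial drive | rate | 0 |

$g(\gamma)$ is always represented as quadrature nodes and weights (a point
mass is one node), so every $\gamma$-integral in the moment equations is a
finite weighted sum and the same code path serves point masses, mixtures and
quadrature approximations of continuous laws.

With $I = 1$, $\beta = 1$, $\bar\gamma \le 1$ the network sits in the
asynchronous regime: the mean drive relaxes to the fixed point
$I/(2\pi - \bar\gamma)$ and per-neuron firing rates are
$\sim (I + \bar\gamma u)/2\pi \approx 0.17$ per time unit. All defaults were
chosen to sit in this regime, where the $1/N$ expansion is expected to hold.

## Numerical design

**Event-driven simulation.** For `linear_phase` with constant $I \ge 0$ and
nonnegative $\gamma$ nodes, $u$ is piecewise exponential and the phase
advance over an interval has the closed form
$I\Delta + \gamma u_k (1 - e^{-\beta\Delta})/\beta$, which is monotone in
$\Delta$; crossing times are found by bisection-safeguarded Newton to
$10^{-12}$ time units. Because the advance is the same for every neuron
sharing a $\gamma$ value, each $\gamma$-group fires in a fixed cyclic order
and only the group head needs a root solve per event — the engine is
$O(G)$ per spike for $G$ distinct coupling values. Signed couplings,
sub-threshold regimes with negative drive, tabulated $I(t)$, and theta
dynamics go through the fixed-step integrator (exact per-step drive decay,
closed-form or RK4 phase advance, in-step crossing location, and exact
superposition of each spike's exponential kick). The identified boundary
node $\theta = -\pi \equiv \pi$ is treated as the post-firing side: a neuron
placed exactly there has a full revolution ahead of it.

**Phase grid.** Fields live on $M$ uniform $\theta$ nodes with node 1 at the
identified firing phase, times the $\gamma$ quadrature; the integration
measure is $\Delta\theta \, w_q$ and the rectangle rule is exact for smooth
periodic integrands up to the grid's Nyquist order.

**Mean field by characteristics.** For `linear_phase` the advection speed
$I + \gamma a_1$ is $\theta$-independent, so each $\gamma$-slice of the
density is a rigid rotation of $\rho_0$ by
$\Phi_\gamma(t) = \int I + \gamma \int a_1$. The solver advances
$(a_1, \int a_1)$ with classical RK4 and evaluates $\rho_0$ at the shifted
firing phase (analytically for uniform/bump, by periodic cubic spline for
tabulated laws) — no grid transport, no diffusion. `wilson_cowan_reduced`
integrates the reduced rate ODE through `deSolve` as an independent route;
the two agree to $10^{-8}$ for uniform initial phases, and the reduction
refuses non-uniform $\rho_0$, where the full conservation equation is
required. For theta dynamics the speed depends on $\theta$ and a
first-order conservative upwind scheme (CFL-guarded) stands in.

**Moment closure stepping.** `solve_gae` uses Strang splitting: half-step of
all source/relaxation terms (explicit midpoint), a full semi-Lagrangian
advection — a rigid rotation per $\gamma$-slice implemented as a circulant
4-point cubic Lagrange shift whose columns sum to one, so density mass is
conserved to round-off — then a second source half-step. $C_{33}$ advects in
both arguments as $S \mapsto \mathrm{Sh}\, S\, \mathrm{Sh}^\top$, which
preserves swap symmetry exactly. A guard subdivides any step whose shift
exceeds `max_shift_factor` cells. Observed self-convergence in `dt` is first
order or better (the splitting interacts with the slaved singular channels
described next).

**Singular structure at the firing line.** The cross-covariance equation
carries a delta source on the firing line, and its solution is a "trail":
a jump at the line of magnitude $J_q$ advected downstream. Advecting a
discontinuity by cubic interpolation rings, so the stepper slaves the
singular structure to analytic profiles and advects only the smooth
remainder:

* the jump rides on a fixed sawtooth $W(\theta) = -\theta/2\pi$ (unit jump
  at the line, midpoint zero there), with amplitude
  $J_q = c\,\beta\,a_3(\pi, \gamma_q)$ — the injection rate divided by the
  advection speed, which cancels because $F = I + \gamma u$ is also the
  speed;
* the kink (slope jump) rides on the continuous parabola
  $K = (x - \pi)^2/4\pi$ with amplitude
  $\kappa_q = (\dot J_q + r J_q)/s_q$, $r$ the relaxation coefficient; the
  pair satisfies $W + K' = 0$ away from the line, which collapses all
  jump-channel sources into smooth terms;
* the density $a_3$ itself acquires an $O(1/N)$ jump at the line (from the
  delta in $\partial_\theta C$ entering its equation) and gets the same
  treatment with amplitude $-(\gamma/N) J_q / s_q$.

Integrals against $\delta(\pi - \theta)$ then sample the field at the line
as the midpoint of its one-sided limits, as delta-function calculus
requires; on the grid this is simply the firing-node value of the smooth
remainder. Where a slice's speed vanishes the channels are clamped and the
delta mass stays on the firing node.

**Cumulant convention for $C_{33}$.** Two readings of the two-point density
covariance are implemented. Under the `ordinary` (raw) convention the
i.i.d.-draw initial condition is the multinomial covariance
$\delta(x - x')\rho_0(x) - \rho_0(x)\rho_0(x')$, whose diagonal self-term is
carried analytically (it rides on $a_3$, which advects at the same speed);
its contribution to the cross-covariance equation collapses onto the firing
line and cancels exactly half of the $2\beta F a_3 \delta(\pi-\theta)$
source. Under the `factorial` (normal-ordered) convention the self-term is
absent and the full $2\beta$ source acts. The package settles the choice
against an oracle that needs no Monte Carlo: for $\gamma \equiv 0$ every
neuron fires deterministically from its initial phase, so
$N\operatorname{Var}(u)$ reduces to a one-dimensional quadrature over the
initial phase. The ordinary convention reproduces that oracle (and raw
Monte-Carlo drive statistics) to a few percent; the factorial one
overshoots by roughly a factor two. `ordinary` is therefore the default,
and the factorial toggle remains for comparison against normal-ordered
statistics.

## What the generators emulate — and what they do not

Initial conditions are product ensembles: phases i.i.d. from $\rho_0$,
couplings i.i.d. from $g(\gamma)$, $u_0$ deterministic. That is exactly the
ensemble over which the moment equations are defined, so Monte-Carlo
agreement validates the closure under its own assumptions. The generators do
**not** emulate features of biological recordings: heterogeneous or sparse
connectivity, synaptic delays, conductance dynamics, intrinsic noise, or
correlated initial states. Passing tests therefore demonstrate the internal
consistency and correctness of the three levels for the globally coupled
deterministic model — not that the closure describes any particular real
network.

## Problem sizes and tolerances

The validation suite runs at desk scale, chosen to keep the full test run in
about a minute while leaving every comparison statistically meaningful:
$M = 64$ phase nodes and $dt = 5\times10^{-3}$ for moment-closure runs to
$T = 10$ ($dt = 10^{-2}$ for $T = 50$ conservation runs); ensembles of
$R = 1000$–$4000$ realizations at $N = 100$–$400$; a dense $dt = 10^{-5}$
fixed-step reference for the simulator oracle. At these settings the
closure's $C_{11}$ sits within about 1–2% of the $\gamma = 0$ quadrature
oracle and within $3$ standard errors of $R = 4000$ ensembles in the coupled
and bump regimes. Refining $M$ further slowly drifts the coupled-case
$C_{11}$ (a residual percent-level sensitivity from the next, unregularized
order of singular structure — curvature jumps in $C$ and jump lines in
$C_{33}$'s smooth part); $M = 64$ is the documented operating point.

## Known limitations

* The moment closure is implemented for `linear_phase` dynamics only, the
  family for which the equations close; theta-model covariances would need
  their own derivation.
* Event-driven simulation requires constant $I \ge 0$ and nonnegative
  coupling nodes (monotone crossing times); everything else uses fixed-step.
* The closure truncates at second cumulants and order $1/N$: strongly
  synchronized regimes, where fluctuations are not small, are outside its
  validity, and the Monte-Carlo engine is the only trustworthy level there.
* Unequal-time covariances are not propagated; all covariance fields are
  equal-time.

## A worked example

```{r example, eval = FALSE}
gl <- gamma_point(0.5)
m <- model_spec(N = 200, beta = 1, drive = 1, gamma_law = gl)
g <- phase_grid(64, gl)

sol <- solve_gae(m, g, T = 10, dt = 5e-3)
ens <- run_ensemble(m, R = 4000, base_seed = 42, grid = g,
                    sample_times = c(1, 5, 10))
compare_moments(sol, ens)
```

The comparison table reports, per quantity and time, the closure prediction,
the ensemble estimate, its standard error and the z-score; in the
asynchronous regime the z-scores stay within $\pm 3$.
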