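---
title: "Methods: eco-evolutionary dynamics of plant-pollinator trait matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary dynamics of plant-pollinator trait matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollevol)
```

## The model and its assumptions

`pollevol` simulates a deliberately minimal plant-pollinator community:
two plant populations (abundances $P_1, P_2$) and two pollinator
populations ($R_1, R_2$) coupled by Lotka-Volterra competition within each
trophic level and by mutualism across levels. The mutualistic benefit
between plant $i$ and pollinator $j$ is maximal when their functional
traits match ($\pi_i = \rho_j$) and decays as a Gaussian in the mismatch,
with a single tolerance width $\sigma$ shared by all populations. A second
parameter $\varphi \in [0,1]$ discounts the *maximal* benefit of the
cross pair (plant $i$ with pollinator $j \ne i$), so that $\varphi = 0$
restricts each pollinator to one plant regardless of trait matching and
$\varphi = 1$ makes the pairs interchangeable. Together $(\sigma,
\varphi)$ span a specialist-generalist continuum.

Key structural assumptions, inherited from the modelled system of
mass-flowering crops and wild pollinators:

* **Pollinators do not compete for floral resources.** Flowers are
  superabundant; pollinator regulation comes from other factors (nesting
  sites, predation), expressed as a shared carrying capacity $K_R$. A
  direct consequence is that a rare mutant's fitness depends on the
  resident community only through its equilibrium abundances, never
  through the resident trait itself, which keeps the invasion analysis
  one-dimensional per pollinator.
* **Plants do not evolve.** They are domesticated crops with fixed traits
  $\pi_1 = 1$, $\pi_2 = 3$; only the pollinator traits $\rho_1, \rho_2$
  are under selection.
* **Everything else is implicit.** Other species and the physical
  environment enter only through the carrying capacities and growth
  rates; there is no stochasticity of any kind. The pipeline is exactly
  deterministic and re-running any configuration reproduces its outputs
  bit for bit.

Because each pollinator is logistically self-regulated under $K_R$ and
mutualism only ever adds growth, neither pollinator can be driven extinct
under the canonical parameterisation; the extinction terminations of the
evolutionary loop become reachable only under engineered parameters (the
test suite exercises them with full competitive overlap, $\alpha = 1$).
Plant extinction, by contrast, does occur within the canonical scenarios:
under strong dominance of Plant 1 both pollinators converge on it and
Plant 2 collapses.

## Parameters

| symbol | code | default | meaning |
|---|---|---|---|
| $\sigma$ | `sigma` | — | width of the trait-matching tolerance (trait units) |
| $\varphi$ | `phi` | — | asymmetry in mutualistic benefit (dimensionless, $[0,1]$) |
| $\theta$ | `theta` | 0.1 | maximal intrinsic mutualistic benefit (per-capita rate per partner abundance) |
| $\alpha$ | `alpha` | 0.5 | interspecific competition within a trophic level |
| $r_m$ | `r_m` | 1 | maximal intrinsic growth rate (sets the timescale) |
| $K_1, K_2$ | `K1`, `K2` | 2, 2 | plant carrying capacities |
| $K_R$ | `K_R` | 1 | shared pollinator carrying capacity |
| $\pi_1, \pi_2$ | `pi1`, `pi2` | 1, 3 | fixed plant trait values |

`sigma` and `phi` have no defaults because they define the specialisation
scenario under study; the canonical grid is $\sigma \in \{0.25, 0.5,
\ldots, 2\}$ and $\varphi \in \{0.25, 0.5, 0.75\}$. With $|\pi_1 - \pi_2|
= 2$, interactions are effectively specialised for $\sigma \le 1$. The
published table of parameter values is reproduced exactly by
`model_parameters()` defaults, and $\theta = 0.1$ is small enough to
prevent runaway mutualistic growth across the whole grid. The pollinator
carrying capacity appears in some sources under two names (one in the
parameter table, one in the equations); there is a single such quantity
and the code calls it `K_R`.

## Solving the ecological equilibrium

`find_equilibrium()` integrates the ODEs with `deSolve::lsoda` (adaptive
step, `rtol` $10^{-9}$, `atol` $10^{-12}$) in growing time chunks, then
declares stationarity when $\max|dX/dt| < 10^{-9}$ (`tol_eq`) sustained
over a trailing window of 10 model-time units. Any controlled-tolerance
integrator is adequate here — the dynamics are non-stiff at these
parameters — and `tol_eq` is deliberately three orders of magnitude below
the $10^{-3}$ extinction threshold and below the $10^{-6}$ gradient
threshold, so equilibrium error never decides a termination. The horizon
is $T_{\max} = 10^5$; failing to reach stationarity by then is reported
via `converged = FALSE`, not an error, and downstream operations refuse
unconverged equilibria.

Numerical details worth knowing:

* **Negative abundances.** Trajectories starting non-negative cannot
  mathematically cross zero, but integrator round-off can produce tiny
  negatives. Components in $(-10^{-12}, 0)$ are clipped to exactly zero
  (`eps_clip`); anything at or below $-10^{-12}$, or non-finite, aborts
  with a blow-up diagnostic rather than being masked.
* **Newton refinement.** After integration the state is polished by a
  damped Newton solve on the right-hand side using the analytic Jacobian,
  restricted to components above $10^{-3}$ — near-extinct components are
  left to the integrator, since Newton steps could move them across zero.
  This removes residual integrator drift (typical polished residuals are
  $10^{-13}$), which matters because selection gradients are read off
  equilibrium abundances.
* **Starting states and basins.** Zero abundance is absorbing, and the
  system has competitive-exclusion attractors alongside interior ones (a
  cold interior start at, say, $\sigma = 2$, $\varphi = 0.75$, $K_1 = 1$
  collapses Plant 1). The perturbation experiments therefore always start
  the perturbed-$K_1$ equilibrium from the *baseline* equilibrium
  abundances — the state the community actually occupied when the
  carrying capacity changed — and the evolutionary loop warm-starts each
  equilibrium from the previous step's. Cold starts default to the
  interior point $(K_1/2, K_2/2, K_R/2, K_R/2)$, which avoids trivial
  extinction basins. The published results appear equilibrium-dominated;
  exact basin boundaries at extreme parameters are not charted here.

## The evolutionary loop

`evolve_to_ess()` implements classical adaptive dynamics: mutations are
rare (the community is at ecological equilibrium when one arises) and
small. The invasion fitness of a mutant and its derivative at the
resident trait — the selection gradient $s_i$ — are evaluated
analytically; the test suite holds the analytic gradients to within
$10^{-6}$ of central finite differences of the invasion fitness across a
thousand randomised configurations.

The trait-substitution dynamics are deterministic gradient ascent: both
traits move simultaneously by $h\,s_i$, with $h$ chosen each step so the
larger trait change equals $\min(\delta_{\max},\, \max(|s_1|, |s_2|))$,
$\delta_{\max} = 0.01$ trait units. The canonical equation of adaptive
dynamics prescribes a rate *proportional* to the gradient with a constant
involving mutation rate and variance that the study system leaves
unspecified; since a positive rate constant only rescales evolutionary
time, ESS locations and termination outcomes are unchanged by this
choice, which is why the simulator does not expose a mutational constant
at all. $\delta_{\max} = 0.01$ is small against the trait scale
($|\pi_1 - \pi_2| = 2$), honouring the small-mutation assumption; the
test suite halves it and recovers terminal traits to $10^{-4}$.
Simultaneous (rather than alternating) updates preserve the model's
mirror symmetry exactly, so the symmetric baseline yields exactly
mirror-imaged traits and equal abundances. A safeguard halves $h$ if a
step inflates $\max|s_i|$ more than tenfold (overshoot near sharp
landscapes, only relevant at small $\sigma$).

Termination mirrors the published algorithm exactly: an ESS when
$\max(|s_1|, |s_2|) < 10^{-6}$; a pollinator extinction when its
equilibrium abundance falls below $10^{-3}$ while the survivor's gradient
is below threshold (the extinct pollinator is frozen — abundance
effectively zero, trait no longer updated — while the survivor finishes
converging); a plant extinction when a plant falls below $10^{-3}$ while
a pollinator sits at an ESS adapted to the other plant. The iteration cap
of $10^5$ steps is generous for $\delta_{\max} = 0.01$ over a trait range
of 2 and is reported as a status, never an exception.

Initial traits for the baseline ESS are $\rho_i = \pi_i$ — each
pollinator matched to "its" plant — and every perturbation experiment
starts evolution from the baseline ESS traits. For $\sigma \le 0.5$ the
baseline ESS is numerically indistinguishable from $(\pi_1, \pi_2)$
itself: the cross-plant pull is
$\mathcal{O}(e^{-\frac{1}{2}(2/\sigma)^2})$, which at $\sigma = 0.25$ is
below the gradient threshold from the start. One nuance: at $\sigma =
0.5$, $K_1 = 3$ the ESS does shift, by about $1.3 \times 10^{-3}$ trait
units — real but invisible at figure resolution, which is what "no
evolution for specialists" means quantitatively.

## Diversity metrics and extinction semantics

Species evenness is the Gini-Simpson index scaled by 2 so that two
equally abundant species score 1; functional diversity is Rao's quadratic
entropy, the abundance-weighted expected trait distance. When metrics are
reported for terminal states, abundances below the $10^{-3}$ extinction
threshold are zeroed first, so that "functional diversity loss" and
"species loss" use the same extinction semantics as the evolutionary
algorithm. The quadratic entropy is bounded by half the trait gap, with
equality at even abundances — so convergent evolution (trait gap
$\to 0$) annihilates it even while evenness is fully restored.

## The experiments

`sensitivity_table()` reproduces the short-timescale response surface:
per $(\sigma, \varphi)$, evolve the baseline ESS at $K_1 = K_2 = 2$,
freeze traits, solve equilibria over $K_1 \in \{1, 1.25, \ldots, 4\}$ (13
points), and take OLS slopes of $R_1^*$ and $R_2^*$ on $K_1$. The
response is linear to $R^2 \ge 0.999$, so the grid choice is immaterial
at the reported precision (a 2-point difference gives the same three
decimals); 13 points are kept for the regression diagnostics. Frozen
baseline-ESS traits (rather than plant-matched $\rho = \pi$) are the
convention for the "before evolution" state throughout; for $\sigma \le
0.5$ the two coincide. The acceptance script recomputes selected cells of
this table from scratch; the full-grid test holds all 48 slopes to within
$\pm 0.01$ of the published three-decimal values.

`diversity_before_after()` and `benefit_curve()` quantify the
eco-evolutionary response: "before" is the equilibrium at the new $K_1$
with frozen baseline traits, "after" the re-evolved ESS. The Rao-Q
surfaces are keyed by relative plant abundance $K_1/(K_1+K_2)$ with $K_2
= 2$ fixed, matching the design in which only $K_1$ varies (total plant
abundance grows left to right, so the surfaces are not symmetric).

One property worth flagging because it is easy to over-generalise:
stronger mutualism ($\theta \uparrow$) raises *every* equilibrium
abundance only in the symmetric configuration $K_1 = K_2$. Under
asymmetric carrying capacities the dominant plant's gain propagates as a
competitive loss to the other plant and its pollinator — an
indirect-effect chain, not a numerical artifact — and the test suite
checks monotonicity only where it genuinely holds.

## What the fixtures emulate, and what they do not

The package ships no data; `generate_fixtures()` writes the 24 canonical
scenario configurations, the $K_1$ sweep specification, and three reduced
scenarios with closed-form expectations ($\theta = 0$ Lotka-Volterra
limit, single-pollinator community, symmetric baseline) that anchor the
solver tests analytically. These scenarios are the study conditions, not
approximations of field data: real plant-pollinator networks have many
species, resource competition among pollinators, stochastic environments,
and evolving plants. Passing tests therefore demonstrate the internal
correctness of the model and the reproduction of its published behaviour,
not predictive accuracy for any empirical community.

## Problem sizes and runtime

The default test suite solves a few thousand ecological equilibria and a
few dozen full evolutionary runs; the complete 24-scenario sensitivity
table takes well under a minute on one core (each scenario is a baseline
evolution of 1-300 steps plus 13 equilibrium solves, each solve a few
milliseconds thanks to warm starts and Newton polish). Baseline ESS
results are cached per $(\sigma, \varphi)$ within a session.

## Known limitations

* Diversity formulas are hard-wired to the two-species community; there
  is no $n$-species generalisation here.
* The trait-substitution sequence is deterministic; stochastic mutant
  draws (and therefore branching *dynamics*, as opposed to branching-point
  classification via `classify_singularity()`) are out of scope.
* Plant traits never evolve, and there are no time-varying or stochastic
  environments.
* Basin structure is handled by the warm-start policy rather than mapped
  exhaustively; scenarios far outside the canonical grid should be
  checked for multistability before trusting a single equilibrium.
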