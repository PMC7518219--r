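---
title: "Motivation-gated learning of aesthetic values: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motivation-gated learning of aesthetic values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`aestheval` simulates an agent that learns how much it values sensory
inputs from the rewards obtained by acting on them. Three components
define the model:

1. **Inputs.** A two-dimensional sensory vector `u = (u_b, u_c)` — visual
   balance and visual complexity, abstract coordinates on `[0, 1]` — drawn
   i.i.d. from a bivariate Gaussian truncated to the unit square. The
   standard parameters put both means at 0.5 with standard deviation 0.2
   and correlation −0.5: balanced (organized) images tend to be simpler,
   which is the empirically motivated coupling the competition analyses
   probe.

2. **Rewards.** Acting on an input returns `r* = r_b + r_c`, two
   conditionally independent Gaussian components. The balance component has
   mean `-alpha + 2 alpha u_b`: linear, zero integral over the input range,
   so positive and negative rewards balance. The complexity component has
   an inverted-U mean `phi + beta exp(-(u_c - gamma)^2 / (2 theta^2))`,
   with `phi` fixed in closed form (via the Gaussian CDF) so this curve
   also integrates to zero — moderate complexity is rewarding, very little
   or very much is punishing. Reward noise is *not* truncated: negative
   rewards are part of the model.

3. **Motivation.** A deterministic function of complexity,
   `m(u_c) = m_min + (m_max - m_min) exp(-(u_c - mu_m)^2 / (2 sigma_m^2))`,
   interpreted as the propensity to act. It gates the received reward
   (`r = m r*`), the value estimate (`v = m (w . u)`), and hence — through
   the prediction error `delta = r - v` — the learning rate of the delta
   rule `w' = w + epsilon m (r* - w . u) u`. Motivation appearing on both
   sides is the model's central asymmetry: without motivation there is no
   reward, no value, and no learning. Only the mean-field motivation is
   simulated; stochastic motivational states around that mean are a
   documented extension point, not implemented, which matches the model's
   own simplification.

The value function is linear in the input. That is an assumption of
convenience: the fast-then-slow dynamics, near-optimality and value
exaggeration discussed below depend on the delta rule and on the input and
motivation statistics, not on linearity, but none of the nonlinear
generalizations are implemented here.

## Parameters

All parameters are unitless (inputs and motivation live on `[0, 1]`,
rewards on an arbitrary reward scale). `standard_parameters()` returns the
standard set:

| group | parameters | standard values | role |
|---|---|---|---|
| sensory | `mu_b, mu_c, sigma_ub, sigma_uc, rho` | 0.5, 0.5, 0.2, 0.2, −0.5 | truncated-Gaussian input density |
| reward | `alpha, sigma_rb` | 0.6, 0.1 | balance reward slope, noise |
| reward | `beta, gamma, theta, sigma_rc` | 1, 0.75, 0.1, 0.1 | complexity bump height, location, width, noise |
| motivation | `m_min, m_max, mu_m, sigma_m` | 0.1, 0.6, 0.65, 0.1 | motivation floor, peak, peak location, width |
| learning | `w0, epsilon` | (0, 0), 0.01 | initial weights, step size |

Validation is deliberately split from construction: constructors accept
any numeric values so that candidate parameter sets can be built and
reported on, `validate_individual()` lists every violated bound by name,
and every sampler or analysis refuses an invalid individual. Sensory
*means* outside `[0, 1]` only warn — the truncation constrains samples,
not means. `theta` enters the bump only squared; we require it positive as
a convention.

Two conventions are fixed package-wide because the model itself does not
fix them: weight/input index 1 is balance and index 2 is complexity; and a
"society" or population is a list of individuals with hand-set parameters
(the `background` field is a label, never a sampling distribution).

## What the generator emulates — and what it does not

The synthetic environment reproduces the *statistical structure* the model
posits: truncated-Gaussian input clouds with negative balance–complexity
correlation, zero-mean reward curves with Gaussian noise, and a
unimodal motivation profile. It does not compute balance or complexity
from actual images, does not model social transmission of parameters, and
draws inputs i.i.d. over time (no temporal autocorrelation in what the
agent sees). Passing tests therefore demonstrate the internal consistency
of the learning theory under its own assumptions — not that human
aesthetic learning has these statistics.

## Numerical choices

**Sampling.** The truncated bivariate Gaussian is sampled by exact
rejection from the untruncated Gaussian (`MASS::mvrnorm` proposals kept if
inside the unit square). At the standard parameters about 97% of proposals
are accepted; a budget of `1000 * n` proposals guards against parameter
sets with negligible mass in the square, which are reported as degenerate
rather than silently looped on. One RNG stream per simulation, seeded from
the configuration, with all sensory draws generated first, then the
balance-reward noise, then the complexity-reward noise; trajectories are
bit-reproducible from their manifest.

**Quadrature.** All expectations under the truncated density (the moment
matrix `A`, cross-moment `b`, and the error functional `E(w)`) use a
fixed-order Gauss–Legendre product rule on `[0, 1]^2` with 80 nodes per
axis. The narrowest features — the reward bump and motivation bump, both
of width 0.1 — need roughly that resolution; the test suite verifies that
doubling the order changes `A` and `w*` by less than `1e-10`, and an
independent adaptive-quadrature route (`pracma::integral2` plus `optim`)
recovers the same minimizer. `E(w)` uses the algebraic identity
`(r - v)^2 / m = m (r* - w . u)^2`, valid whenever motivation is positive;
for identically zero motivation the functional is 0/0 and the package
reports it undefined instead of returning a number.

**Integration step and stability.** `epsilon = 0.01` with unit time step
is the standard configuration. Because `||u||^2 <= 2` and `m <= 1`, the
per-sample contraction factor `1 - epsilon m ||u||^2` stays inside the
unit interval with a wide margin, and each update strictly shrinks that
sample's residual. A divergence guard aborts if any weight exceeds `1e6`
in magnitude — which signals an oversized `epsilon`, since the exact
dynamics cannot reach such values.

**Horizons.** The default horizon is 30,000 steps, the horizon of the
shipped experiments, with cloud sampling from step 10,000 at stride 200
where clouds are compared. The slowest relaxation time of the standard
error surface is `1 / (epsilon lambda_min) ≈ 9,300` steps, so a 30,000-step
run is long enough to display the dynamics but its late window still
carries a small transient for conditions with large equilibrium weights.
The fixed-point recovery analysis therefore uses 150,000 steps and
averages the last third, across 10 seeds per condition, comparing the
across-seed mean to `w*` within three empirical standard errors. Three
standard errors is our choice of agreement criterion; the model itself
supplies no tolerance.

## Quantifying "apparent competition"

The competition between the two weights — one rising while the other falls
during late learning — is a qualitative, visual notion. We operationalize
it with two complementary statistics (`competition_metrics()`):

* `separation`: the late-window mean of `w_c - w_b`. This measures where
  the weights end up, and is the right statistic for the standard
  condition (clearly positive) and for exactly symmetric ablations (zero).
* `divergence`: the change in separation from the first to the last third
  of the observation window. This measures whether the weights are *still*
  moving apart, and is the right statistic for the constant-motivation
  ablations: with `m ≡ 1` the dynamics equilibrate several times faster
  (relaxation time a few thousand steps), so over the observation window
  the weights just hover around their equilibrium — no sustained
  divergence, no apparent competition — even though the equilibrium
  separation itself need not vanish. A single end-state separation
  statistic cannot express this distinction, which is why both are
  reported.

The per-step increment correlation is also reported, with a caveat
documented on the function: at stride 1 both increments are the same
scalar times the (positive) input components, so the correlation is only
informative on trajectories thinned beyond the fast mixing time.

Ablation knobs are named presets (`ablation_variant()`): input correlation
removed (`rho = 0`), reward structures made identical (the complexity
reward takes the linear balance form with the same slope and noise), and
motivation made constant (`m ≡ 1`). Alternative knob definitions are one
configuration edit away.

## Value landscapes and probes

`value_landscape()` evaluates `V(u) = m(u_c) (w . u)` on a grid and
reports the argmax alongside the input-density mode — the
value-exaggeration comparison. The value at a probe includes the
motivation factor at that probe, consistent with the value definition; the
default probe set places one probe at the density mode and one in each
quadrant center, and is fully configurable since any particular probe
layout is a presentational choice.

## Known limitations

* Two input dimensions only in the shipped experiments (the update itself
  is dimension-agnostic, but nothing else is exercised beyond N = 2).
* Mean-field motivation only; no stochastic motivational states.
* Linear value function only.
* No fitting to empirical data: the package is a simulator and analysis
  tool for the theory, not an estimation framework.
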