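# aestheval

Simulation and analysis of a reinforcement-learning account of how
aesthetic values form. The package is aimed at computational
neuroscientists and empirical-aesthetics researchers who want a tested,
reproducible implementation of a motivation-gated delta-rule learner over
stochastic sensory inputs, together with the equilibrium and landscape
analyses that explain its behaviour.

## The model

An agent observes sensory inputs `u = (u_b, u_c)` — visual **balance** and
visual **complexity**, both in `[0, 1]` — drawn from a bivariate Gaussian
with means `(mu_b, mu_c)`, standard deviations `(sigma_ub, sigma_uc)` and
correlation `rho`, truncated to the unit square. Acting on an input yields
a stochastic reward `r* = r_b + r_c`, with a linear balance component
(mean `-alpha + 2 alpha u_b`) and an inverted-U complexity component
(mean `phi + beta exp(-(u_c - gamma)^2 / (2 theta^2))`, with `phi` chosen
so the mean integrates to zero over `[0, 1]`). A motivation function of
complexity,

    m(u_c) = m_min + (m_max - m_min) exp(-(u_c - mu_m)^2 / (2 sigma_m^2)),

gates everything: the received reward is `r = m r*`, the estimated reward
(aesthetic value) is `v = m (w . u)`, and the weights learn by the
discretized delta rule

    w(t_{k+1}) = w(t_k) + epsilon m(u_c) (r* - w . u) u .

With zero motivation, learning freezes. The learning process minimizes the
motivation-conditioned expected squared error
`E(w) = < (r - v)^2 / m >`, a positive-definite quadratic form in `w`
whose unique minimizer `w* = A^{-1} b` (with `A = E[m u u']`,
`b = E[m rbar* u]` under the truncated input density) the package computes
by Gauss–Legendre quadrature. The stochastic weights hover around `w*` on
a hammock-shaped error surface; each sample constrains them only to an
iso-value line `m u . w = v`, which is why redundant weight combinations
drift while value stays put.

## Worked example

```r
library(aestheval)

std  <- standard_parameters(n_steps = 30000, seed = 42)
traj <- run_simulation(std$individual, std$config)
traj
#> <aesthetic_trajectory> 30001 recorded steps (horizon 30000, epsilon 0.01, seed 42)
#>   final weights: w_b = 0.0739, w_c = 0.1961

fixed_point(std$individual)
#> <fixed_point> w_star = (0.0595, 0.1881), curvature anisotropy = 14.81

competition_metrics(traj)$separation
#> [1] 0.1140

land <- value_landscape(fixed_point(std$individual)$w_star,
                        std$individual$motivation,
                        sensory = std$individual$sensory)
land
#> <value_landscape> argmax V = 0.1097 at (1.000, 0.660); V at density mode (0.500, 0.500) = 0.0325
```

What the numbers mean: starting from ignorance (`w = (0, 0)`), the agent's
complexity weight (0.196) ends well above its balance weight (0.074) — the
two weights appear to compete, and the late-window separation of 0.114
quantifies it. The simulated weights agree with the quadrature fixed point
`w* = (0.0595, 0.1881)`, the minimizer of the expected error; the error
surface around it is 15 times steeper in one direction than the other,
which is why learning is fast at first and then drifts slowly along the
shallow bed. The learned value landscape peaks at exaggerated balance and
complexity `(1.00, 0.66)` with value 0.110, more than three times the
value 0.032 of the most typical input `(0.5, 0.5)`: value exaggeration,
the model's account of the peak-shift effect in art.

The scripted experiments (`experiment_dynamics()`,
`experiment_error_descent()`, `experiment_competition_ablations()`,
`experiment_individuality()`, `experiment_value_probes()`) reproduce the
full set of study conditions and write CSV outputs with JSON manifests; a
thin command-line front end lives at `inst/cli/aestheval.R`. See the
vignette (`vignettes/aesthetic-learning.Rmd`) for the model's assumptions,
parameter meanings, and numerical choices.

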