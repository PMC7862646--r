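# netswitch

Densification and sparsification of a temporal social network — the rise and
fall of the number of active nodes *N* and edges *M* from one snapshot to the
next — can come from two fundamentally different sources: people entering or
leaving the system (a change in the latent *potential population*
N<sub>p</sub>), or people in the system becoming more or less likely to
interact (a change in the *overall activity* κ). `netswitch` takes a sequence
of per-window counts (N<sub>t</sub>, M<sub>t</sub>) from face-to-face contact
data and infers, window by window, which of the two mechanisms is driving the
dynamics, together with the full paths of the latent population and activity.

The package is aimed at researchers working with SocioPatterns-style RFID
proximity data (conferences, hospitals, schools, workplaces) and, more
generally, at anyone with a time series of network sizes and edge counts who
wants to separate population-driven from activity-driven dynamics.

## Model

Within a window, two nodes *i*, *j* are in contact with probability

    P_ij = κ a_i a_j,     a_i ~ Uniform[0, 1],

where `a_i` is a node's intrinsic activity (fitness) and κ modulates the
overall rhythm. With N<sub>p</sub> potential nodes this gives closed forms

    N  = N_p [ 1 − (2/(κ N_p)) (1 − (1 − κ/2)^{N_p}) ]
    M  = (1/8) κ N_p (N_p − 1)

Eliminating one parameter yields two one-parameter curves in the (M, N)
plane:

* **Regime 1** (population-driven): N = h¹(M; κ), population varies via
  N<sub>p</sub>(M, κ) = (1 + √(1 + 32M/κ))/2 at constant κ — a
  near-constant-slope densification scaling;
* **Regime 2** (activity-driven): N = h²(M; N<sub>p</sub>), activity varies
  via κ(M, N<sub>p</sub>) = 8M/(N<sub>p</sub>(N<sub>p</sub>−1)) at constant
  N<sub>p</sub> — an accelerating, "explosive" scaling.

Observed counts follow N<sub>t</sub> = h^s(M<sub>t</sub>) + ε<sub>s,t</sub>
with Gaussian errors and a hidden two-state Markov chain S<sub>t</sub>
switching between the regimes with stay-probabilities p₁₁, p₂₂. The constant
parameters θ = {N<sub>p</sub>, κ, σ₁, σ₂, p₁₁, p₂₂} are estimated by MCMC
(adaptive random-walk Metropolis started at the Laplace approximation);
state probabilities come from the Hamilton filter and Kim smoother. Windows
are classified Regime 1 / Regime 2 / "gray" according to whether more than
95 % of posterior draws put the smoothed regime probability above or below
0.5, and the latent paths are reconstructed as probability-weighted mixtures
of the two branch estimates.

## Worked example

Simulate a switching contact system (base population 200, base activity 0.3,
both stay-probabilities 0.95, per-window decay 0.95 of whichever parameter is
active), then fit and classify:

```r
library(netswitch)
cfg <- sim_config(n_potential_base = 200, kappa_base = 0.3,
                  p11 = 0.95, p22 = 0.95, n_windows = 200, seed = 42)
sim <- simulate_series(cfg)
sim
#> Synthetic regime-switching dataset: 200 windows
#>   regime 1 in 43 windows; base N_p = 200, base kappa = 0.3

fit <- run_mcmc(sim$series, n_keep = 750, n_burn = 1500, seed = 7)
posterior_summary(fit)
#>     parameter    mean  ci_low ci_high             prior
#> 1 n_potential 200.396 199.559 201.192 Uniform(198, 396)
#> 2       kappa   0.297   0.290   0.305     Uniform(0, 1)
#> 3      sigma1   5.873   4.711   7.460 Half-Cauchy(0, 2)
#> 4      sigma2   3.750   3.336   4.201 Half-Cauchy(0, 2)
#> 5         p11   0.918   0.835   0.973        Beta(5, 1)
#> 6         p22   0.976   0.948   0.992        Beta(5, 1)

pd <- smoothed_prob_draws(fit, sim$series, thin = 5)
table(classify_windows(pd))
#> regime1 regime2
#>      46     154
```

The posterior means recover the generating values (N<sub>p</sub> = 200,
κ = 0.3, p₁₁ = p₂₂ = 0.95) and the window classification recovers the true
regime in essentially every window; `parameter_paths()` then gives
per-window population and activity estimates with 95 % credible bands, and
`regime_report()` joins everything into one table.

Real data enter through `read_contacts()` (SocioPatterns `t i j` event
lists, 20-s resolution) and `build_snapshot_series()` (10-minute windows by
default). The same workflow is scriptable from a shell via the CLI wrapper
(`inst/cli/netswitch.R`) with subcommands `simulate`, `window`, `fit`,
`classify`, `report`.

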