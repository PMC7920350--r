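# mobfit

Fitting fine-scale human-mobility models to spatially aggregated
origin–destination (OD) flow data.

## Why

Trip counts derived from mobile-phone call detail records are published
between administrative units, but epidemic simulations and service-planning
models need mobility at the kilometre scale. `mobfit` fits gravity and
radiation models *specified on a fine population grid* to admin-level
counts: the model's expected flow between two administrative units is the
sum of its expected flows over all pairs of grid cells belonging to those
units, and the observed counts enter a negative binomial likelihood around
these aggregated expectations. The same machinery fits directly at the
administrative scale.

## Models

Gravity model with an offset power-law kernel (directional form):

    GM_ij = 10^kappa * m_i^alpha * m_j^beta / (1 + (d_ij / 10^gamma)^epsilon)

with a symmetrised form (scaling `10^(kappa - gamma*epsilon)`, numerator
`m_i^a m_j^b + m_j^a m_i^b`, constraint `alpha > beta`) for undirected data.
Four radiation variants RM1–RM4 replace the kernel with the ring population
`r_ij` (population inside the circle of radius `d_ij` around the origin,
excluding both endpoints):

    RM_ij = T_i * (m_i + theta) * m_j /
            ((m_i + theta + r_ij + m_j) * (m_i + theta + r_ij))

where `theta = 0` for RM1/RM2 and the travellers term `T_i` is
`kappa*m_i` (RM1), `10^kappa*m_i^alpha` (RM2, RM4) or `10^kappa*m_i` (RM3).
Counts are negative binomial with variance `M + disp*M^2`; `disp = 0` is
Poisson. Inference is LHS-seeded adaptive Metropolis MCMC (4 chains, split
R-hat convergence assessment, pooled posterior summaries).

Everything is testable offline: a synthetic-data module generates clustered
("few dominant centres") and dispersed ("sparse, mostly tiny cells")
population rasters, Voronoi administrative partitions and NB-noised flow
datasets from known parameters.

## Worked example

Simulate a clustered 150-cell / 10-unit country, draw undirected OD counts
from the symmetrised gravity model, and fit it back:

```r
library(mobfit)

cfg    <- scenario_preset("clustered", seed = 1)
system <- build_scenario_system(cfg)   # 20 km grid over the synthetic raster
system
#> <spatial_system '20km': 150 cells, 10 units, total population 40000000>

flows <- synth_flows(system, "GM", cfg$params, directional = FALSE,
                     has_diagonal = TRUE, seed = 1001)
flows
#> <flow_dataset: 55 OD pairs, symmetrised, diagonal present, total trips 72872>

fit <- fit_model(system, flows, "GM", symmetrised = TRUE,
                 n_iter = 20000, seed = 1)
fit
#> <mobility_fit: GM (symmetrised), 4 chains, retained from iteration 4001>
#>   parameter      mean       lo95      hi95
#> 1     kappa   -4.8774   -9.54161    0.5244
#> 2     alpha    2.3288    1.70231    2.9232
#> 3      beta    0.2548    0.01205    0.6789
#> 4     gamma    3.2220    2.51568    3.7249
#> 5   epsilon    2.4125    1.64629    3.2533
#> 6      disp    2.0025    1.18989    3.2256
#> 7    loglik -155.0798 -159.95663 -152.4423
#> R-hat: kappa=1.034 alpha=1.009 beta=1.002 gamma=1.022 epsilon=1.025 disp=1.002
```

All chains converge (R-hat at most 1.03) and every generating parameter
(kappa −4, alpha 1.8, beta 0.6, gamma 3.5, epsilon 2.3, disp 1.5) lies
inside its 95% credible interval; 55 noisy observations leave the intervals
wide, which is the honest answer at this data size.

Posterior-predictive checks:

```r
pred <- posterior_predictive_flows(fit, system, n_draws = 100, seed = 2,
                                   nb_noise = TRUE)
cri_coverage(flows, pred)
#> [1] 1

prof <- distance_profile(flows, system, bin_width = 10000)
powerlaw_fit(prof)$exponent
#> [1] 2.540903
```

The observed trip-frequency-by-distance curve decays roughly as a power law
(exponent ≈ 2.5 here), and all 55 observed counts fall inside their 95%
posterior-predictive intervals.

A thin command-line front end over the same functions ships in
`inst/cli/mobfit.R` (`synth`, `grid`, `fit`, `predict`, `report`
subcommands).

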