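---
title: "Fitting fine-scale mobility models to aggregated flow data"
author: "mobfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting fine-scale mobility models to aggregated flow data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobfit)
```

## The problem

Origin-destination (OD) trip counts derived from mobile-phone records are
usually published only between administrative units, while individual-based
epidemic simulations need mobility at the kilometre scale. `mobfit` fits
mechanistic mobility models *specified on a fine population grid* to
admin-level counts: the model's expected flow between two administrative
units is the sum of its expected flows over all pairs of grid cells
belonging to those units,

$$
\mathrm{Model}_{IJ} \;=\; \sum_{c_i \in I}\sum_{c_j \in J}
\mathrm{Model}_{c_i c_j},
$$

and the observed counts are compared with these aggregated expectations
under a negative binomial likelihood. The same machinery fits the models
directly at the administrative scale (each unit is then a single "cell" at
its population-weighted centroid).

## Models

**Gravity model (GM).** The expected flow from cell $i$ (population $m_i$)
to cell $j$ at distance $d_{ij}$ metres is

$$
\mathrm{GM}_{ij} = \frac{10^{\kappa}\, m_i^{\alpha} m_j^{\beta}}
{1 + (d_{ij}/10^{\gamma})^{\varepsilon}},
$$

an offset power-law kernel: finite at $d = 0$ (so within-cell flows are
defined) and power-law decaying beyond the scale $10^{\gamma}$ metres. When
the data cannot distinguish outbound from return journeys the model is
symmetrised,

$$
\mathrm{GM}^{s}_{ij} = \frac{10^{\kappa - \gamma\varepsilon}
(m_i^{\alpha} m_j^{\beta} + m_j^{\alpha} m_i^{\beta})}
{1 + (d_{ij}/10^{\gamma})^{\varepsilon}},
$$

and fitted to the summed counts $f_{ij} + f_{ji}$ with the identifiability
constraint $\alpha > \beta$ (the two powers are exchangeable in this form;
see "Identifiability" below for the $10^{\kappa-\gamma\varepsilon}$
scaling). Within-unit (diagonal) flows are fitted only when the dataset
reports them.

**Radiation models (RM1-RM4).** Radiation models replace the distance
kernel with the *ring population* $r_{ij}$ — the population within the
circle around origin $i$ of radius $d_{ij}$, excluding $m_i$ and $m_j$ (cells
exactly on the circle are included; the package treats the tie inclusively so
$r$ is right-continuous in distance). The flow is

$$
\mathrm{RM}_{ij} = T_i\,
\frac{(m_i+\theta)\, m_j}{(m_i+\theta+r_{ij}+m_j)(m_i+\theta+r_{ij})},
$$

with $\theta = 0$ for RM1/RM2. The travellers term $T_i$ is estimated from
the data: $\kappa m_i$ (RM1, with $\kappa \ge 0$ natural-scale and *not*
capped at 1 — datasets spanning a year contain many more trips than
residents), $10^{\kappa} m_i^{\alpha}$ (RM2 and RM4), or $10^{\kappa} m_i$
(RM3). $\theta$ inflates the origin population, down-weighting short trips.
Radiation models do not define within-unit trips: the diagonal is excluded
everywhere. Symmetrised variants use the transpose sum
$F_{ij} + F_{ji}$, mirroring the numerator sum of the symmetrised gravity
model. Note the within-cell gravity flow at $d=0$ evaluates the directional
kernel to $10^{\kappa} m^{\alpha+\beta}$; we use this single-term value as
the self-flow convention throughout.

**Likelihood.** Counts are modelled as negative binomial with mean
$M_{IJ}$ (the aggregated model flow) and dispersion $disp$:
$\mathrm{Var} = M + disp\cdot M^2$, i.e. size $= 1/disp$. CDR-derived flow
matrices are strongly over-dispersed, so this matters; $disp$ below
$10^{-8}$ switches to the Poisson limit for numerical stability. OD pairs
absent from the input table are treated as *unobserved* (excluded from the
likelihood), not as zeros; observed zeros are ordinary likelihood terms.
Symmetrised datasets contribute each unordered pair once.

## Geography

`build_grid()` bins a fine population raster (planar metre coordinates —
projecting longitude/latitude is the caller's responsibility) into square
cells, dropping empty cells, with population-weighted centroids. Cells are
assigned to the administrative unit contributing most of their pixels (ties:
smallest unit id). Units that end up empty at any grid scale are merged into
their nearest neighbour consistently across scales
(`merge_small_units()`), and `filter_low_pop_cells()` removes
cells at or below a population threshold — at fine scales a large share of
cells hold almost no population and contribute nothing but computation. The
grid origin defaults to the raster's minimum corner; an `origin_offset`
argument exposes the (usually small) sensitivity to grid positioning.

## Inference

The posterior is explored with Metropolis MCMC under independent uniform
priors (defaults: $\alpha, \beta, \varepsilon \in [0,6]$,
$\kappa \in [-15, 15]$ in log10 — natural-scale $[0, 100]$ for RM1 —
$\gamma \in [0,7]$ log10-metres, $\theta \in [0, 10^7]$ persons,
$disp \in [0,10]$). A Latin hypercube scan of the prior box supplies
starting points for 4 chains (the best points by likelihood). Each chain
adapts during the first half of its run and is assessed with split R-hat on
a ladder of candidate burn-in truncations; samples are retained from the
earliest truncation at which all parameters fall below the threshold
(default 1.05).

`fit_model()` uses *joint* Gaussian proposals whose covariance is learned
from the chain history (adaptive Metropolis, global scale tuned to the
classical 0.234 acceptance optimum). We chose joint over single-component
updates deliberately: the GM posterior contains strong ridges — the scaling
constant trades off against the kernel parameters, and $\alpha$ against
$\beta$ — along which coordinate-wise walks mix far too slowly at realistic
chain lengths. Component-wise updates (with per-component scale adaptation)
remain available via `run_chain(mode = "component")`. Default chain lengths
are desk-scale (tens of thousands of iterations, one proposal per
iteration); production fits of the kind reported for national CDR datasets
use two orders of magnitude more and are reachable through `n_iter`.

### Identifiability

Without within-unit counts, and whenever
$10^{\gamma\varepsilon} \ll d^{\varepsilon}$ over the observed distances,
the directional gravity model depends on $\kappa$ and $\gamma$ only through
$\kappa + \gamma\varepsilon$: the likelihood has a ridge, $\gamma$ is
unidentified, and the plain-$10^{\kappa}$ parameterisation mixes poorly.
The symmetrised model therefore uses the $10^{\kappa-\gamma\varepsilon}$
scaling, under which the sampled $\kappa$ *is* the identified combination.
The shipped `"high-contrast"` scenario demonstrates this: it is built
data-rich and low-noise (units spanning ~2 decades of population, 780 OD
pairs, dispersion 0.05) so that $\alpha$, $\beta$ and $\varepsilon$ are
sharply pinned and the *structural* ridge is isolated — the 95% CrI of the
plain-scaling $\kappa$ comes out 3-4 times wider than that of
$\kappa + \gamma\varepsilon$. With noisier or smaller datasets every
parameter is prior-dominated and no single ridge can be isolated, which is
itself instructive. Fitting this scenario uses longer chains (100k
iterations) and a dense LHS screen (2000 points): a sharp posterior in a
wide box is easy to miss during burn-in, and individual chains can
otherwise get temporarily trapped.

A related ridge affects $\theta$ in RM3/RM4 when most flow originates in
cells with $m_i \gg \theta$: $\theta$ is then weakly identified and its
chains mix slowly even when all other parameters have converged.

## Posterior-predictive analyses

`posterior_predictive_flows()` samples parameter vectors from the pooled
retained draws (default 100, without replacement) and computes the
*expected* flow matrix for each; per-pair means and equal-tailed 95% CrIs
summarise them. For calibration against observed counts set
`nb_noise = TRUE`, which layers negative binomial observation noise (with
each draw's $disp$) on the expected flows — with data simulated at the true
parameters this predictive covers ~95% of observed counts, slightly more
for low-count pairs because the NB quantiles are discrete.
`cri_coverage()` reports the covered fraction, `distance_profile()`
accumulates trips into centroid-distance bins (default 10 km) and
`powerlaw_fit()` fits a least-squares line in log10-log10 space over
non-empty bins, reporting the positive decay exponent; the binning and the
estimator are conventions (bin centres as abscissa), exposed as arguments.
`symmetry_statistic()` computes
$F_{ij} = 100 (f_{ij}-f_{ji}) / \max(f_{ij}, f_{ji})$ per pair of a
directional dataset, summarising $|F|$ over unordered pairs.

## Synthetic scenarios

Real inputs of this kind (gridded population rasters, administrative
boundaries, CDR flow matrices) are license-restricted, so the package
generates its own study systems. `synth_population()` allocates a total
population multinomially over a pixel grid with probabilities from a
mixture of isotropic Gaussian clusters plus a uniform background;
`synth_admin()` partitions pixels by nearest seed, with seeds drawn
population-weighted and distance-spread (k-means++ style) so units have
realistic extents; `synth_flows()` draws NB counts around a generating
model's aggregated flows via the Gamma-Poisson mixture, which matches the
likelihood's parameterisation exactly.

Three presets (`scenario_preset()`) define the study conditions used in the
tests:

* `"clustered"` — 40 million people, 85% in 8 Zipf-weighted centres over
  300 x 200 km; a 20 km model grid gives a 150-cell, 10-unit system;
  undirected flows with diagonal counts from the symmetrised GM
  ($\kappa=-4$, $\alpha=1.8$, $\beta=0.6$, $\gamma=3.5$, $\varepsilon=2.3$,
  $disp=1.5$). Typical OD counts range from zero (remote pairs) to ~10^4
  (within large centres), like admin-level CDR matrices.
* `"dispersed"` — 270 000 people, 90% in 25 small equal clusters over
  300 x 300 km with a ~0.3 persons/km^2 background; at a 5 km grid the
  majority of populated cells hold ten or fewer people while carrying a few
  percent of the population, so low-population filtering removes many cells
  but little mass. Directional GM flows with diagonal, 15 units.
* `"high-contrast"` — the ridge demonstration design described above.

What the generator deliberately does *not* emulate: CDR sampling biases
(phone ownership and usage heterogeneity), temporal structure, road- or
travel-time geometry (distances are Euclidean), and irregular
administrative polygons. Passing recovery tests on these scenarios shows
the estimator is correct and calibrated under its own assumptions — not
that those assumptions hold for any particular real dataset.

## Numerical choices and edge cases

* Distance kernel and population powers are evaluated as
  $\exp(\varepsilon(\log d - \gamma\log 10))$ from precomputed logs inside
  the MCMC objective; the objective caches the kernel, the numerator and
  the aggregated matrix and recomputes only the pieces affected by the
  components that changed, which is exact (verified against from-scratch
  evaluation) and makes desk-scale fits take seconds.
* Ring-population ties are inclusive; admin-assignment ties go to the
  smallest unit id; proportions-to-counts rounding is half-up.
* Aggregation conserves total flow over the included entries; radiation
  diagonals are structurally zero and flagged excluded, and within-unit
  cell pairs contribute only to the (excluded) diagonal aggregate.
* Split R-hat returns exactly 1 when between-sequence variance vanishes
  (identical chains) and `Inf` for disjoint constant chains.
* Posterior quantiles use R's default (type 7) rule.
* Degenerate inputs error early and specifically: empty rasters, all-zero
  populations, units emptied by filtering (named), masked pairs without a
  model flow (named), non-positive populations under the gravity model.

## Problem sizes

The shipped tests fit 150-cell / 10-unit systems with 4 chains of 20k
iterations (~30 s each here), the ridge scenario with 4 x 100k (~3 min),
and verify oracle equivalences on systems of up to 100 cells; these sizes
were chosen so the full simulate-fit-recover study, repeated over ten
seeds, completes comfortably on a laptop while leaving the estimator's
behaviour clearly visible. Production-scale fits (thousands of cells,
millions of iterations) use the same code paths; the objective evaluation
cost scales with the square of the cell count.

## Known limitations

* Euclidean distances only; no travel-time or road-network metrics.
* The power-law exponent estimator is binned least squares, adequate for
  the descriptive use here but not a maximum-likelihood tail estimator.
* $\theta$ (RM3/RM4) can be near-unidentified on systems dominated by
  large-population origins; expect wide CrIs and slow mixing for it.
* The sampler is random-walk Metropolis; posteriors with severe
  multimodality would need tempering or ensemble methods, which are out of
  scope.
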