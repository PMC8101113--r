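---
title: "Bayesian disease mapping with bymrisk: model, priors, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian disease mapping with bymrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymrisk)
```

## The model

`bymrisk` estimates small-area disease risk from counts. For areas
$i = 1, \dots, n$ with observed counts $Y_i$ and expected counts $E_i$,

$$Y_i \sim \mathrm{Poisson}(E_i \theta_i), \qquad
\log \theta_i = \beta_0 + x_i'\beta + u_i + v_i ,$$

where $\theta_i$ is the relative risk of area $i$ against the reference
rate, $x_i$ are area-level covariates, $u$ is a spatially structured random
effect and $v_i \sim N(0, \sigma_v^2)$ is unstructured heterogeneity. This
is the Besag-York-Mollié (BYM) convolution model. The structured effect has
an intrinsic conditional autoregressive (ICAR) prior on an adjacency graph:
each $u_i$ given its neighbours is
$N(\bar u_{\delta_i},\, \sigma_u^2 / n_{\delta_i})$, with $\delta_i$ the
neighbour set and $n_{\delta_i}$ its size. The joint ICAR density is
improper — it is flat along per-component constants — so each draw of $u$
is constrained to sum to zero within every connected component of the
graph. The non-spatial variant drops $u$ and $v$, leaving a Poisson
regression with offset $\log E_i$.

### Expected counts

`compute_expected_counts()` uses internal (indirect) standardization:
$E_i = \mathrm{pop}_i \times \sum_j Y_j / \sum_j \mathrm{pop}_j$, the count
each area would see at the pooled study rate. This is the standard
disease-mapping default when no external reference rates are available, and
it makes $\sum_i E_i = \sum_i Y_i$ exactly, so the population-weighted mean
SMR is 1 and relative risks are centred near 1 by construction. Whether an
age-adjusted or externally standardized $E_i$ is preferable depends on the
application; only internal standardization is computable from a bare
count/population table, which is why it is the default here.

### Priors

Published analyses in this area often lean on a software package's
"default priors"; ours are explicit and vague:

* intercept $\beta_0$: improper flat;
* coefficients $\beta_k \sim N(0, 31.62^2)$ (precision $10^{-3}$);
* precisions $1/\sigma_u^2,\ 1/\sigma_v^2 \sim \mathrm{Gamma}(1,\ 5\times
  10^{-5})$ (shape, rate).

All four are configurable through `bym_priors()`. With counts in the
hundreds per area the likelihood dominates these priors; sensitivity is a
concern mainly for the variance parameters when the number of areas is
small.

## Sampling

`fit_bym()` runs a Metropolis-within-Gibbs sampler written in C++:
random-walk Metropolis updates for $\beta_0$, each $\beta_k$, each $u_i$
and each $v_i$, then conjugate Gibbs draws

$$1/\sigma_u^2 \mid u \sim \mathrm{Gamma}\!\left(a + \tfrac{n - G}{2},\;
  b + \tfrac12 \sum_{i \sim j}(u_i - u_j)^2\right), \qquad
1/\sigma_v^2 \mid v \sim \mathrm{Gamma}\!\left(a + \tfrac{n}{2},\;
  b + \tfrac12 \sum_i v_i^2\right),$$

with $G$ the number of graph components ($n - G$ is the rank of the ICAR
structure matrix). After every sweep $u$ is re-centred to mean zero within
each component; islands (areas with no neighbours) keep $u_i = 0$ and are
carried by $v_i$ alone.

Numerical choices worth knowing:

* **Adaptation.** Proposal SDs follow Robbins-Monro adaptation toward an
  acceptance rate of 0.44 (the scalar-update optimum) *during burn-in
  only*, then freeze, so the retained chain targets the exact posterior.
* **Identifiability.** Classic BYM is only sum-identified: the data inform
  $u_i + v_i$, not the split. $\theta_i$, $\beta$, and $\sigma$-totals are
  the reliable outputs; individual $u_i$/$v_i$ summaries are weakly
  identified. In parameter-recovery runs with a small true $\sigma_v$, its
  posterior quantiles show this clearly (interval coverage for
  $\sigma_v^2$ well below nominal even when $\beta$ coverage is on
  target).
* **Determinism.** Chain $c$ runs under `set.seed(seed + c - 1)` using R's
  RNG from compiled code, so every result — including pipeline CSV output —
  is bit-reproducible for a fixed seed.
* **Zero counts** are fully supported ($\theta_i > 0$ keeps the
  log-likelihood finite); degenerate graphs (isolated areas, multiple
  components) are handled by the per-component constraint.
* **Covariates** are standardized to zero mean / unit SD by default, so
  effects are per-SD and the vague coefficient prior is scale-free; missing
  covariate cells are mean-imputed with a warning (or rows dropped, by
  option). `run_recovery_study()` converts posterior summaries back to the
  raw covariate scale before comparing against generating values, so the
  sample-SD jitter of a simulated covariate does not distort coverage.

Convergence is monitored with rank-normalized split R-hat
(`gelman_rubin()`), warning above 1.05. The shipped defaults
(4 chains x 20,000 iterations, half burn-in, thin 5) suit real analyses;
the test suite and validation studies use shorter chains sized so that a
complete run stays in the minutes range on a single core.

## Posterior summaries

`summarize_relative_risk()` reports, per area, the posterior mean of
$\theta_i$, the equal-tailed 95% credible interval (quantile interval, not
HPD — matching the interval convention of mainstream Bayesian disease
mapping outputs), and exceedance probabilities $P(\theta_i > c)$ computed
with a strict inequality, for thresholds defaulting to $c \in \{1, 1.5,
2\}$. A covariate is flagged "significant" when its 95% credible interval
excludes zero. Ties in `rank_areas()` break alphabetically so ranked output
is reproducible.

## The synthetic-data generator

`simulate_bym_data()` draws data from exactly the model above: independent
Gaussian covariates, an exact ICAR field (spectral decomposition of the
structure matrix with zero-eigenvalue modes removed — not conditional
sweeps — which is fast and exact for $n$ up to a few thousand), i.i.d.
Gaussian $v$, uniform populations, and generating expected counts
$E_i = \mathrm{pop}_i \times$ a baseline rate of 150 per 100,000 — a
realistic order of magnitude for an older-male cancer incidence rate, and
explicit so the generating truth is unambiguous. Fitting still recomputes
$E_i$ by internal standardization, as with real data.

What passing recovery tests show — and what they do not: the generator
matches the model, so recovery validates the sampler and the summaries,
not the model's adequacy for real data. Real county tables have correlated
covariates, spatially structured covariate fields, non-uniform population
sizes, and possibly extra-Poisson variation beyond the latent fields; none
of those are emulated by default (a covariate-correlation option exists but
is off).

The default validation geography is a 20 x 20 rook lattice with
$\beta_0 = 0.1$, one covariate effect of 0.3, $\sigma_u = 0.5$,
$\sigma_v = 0.1$ — moderate spatial structure with modest unstructured
noise, the regime areal smoothing is designed for.

## Adjacency

Graphs come from GAL or edge-list files (`read_neighbor_list()`), from
polygon contiguity (`queen_contiguity()`), or from generators
(`lattice_graph()`, `ring_graph()`). Queen contiguity — areas sharing any
boundary point are neighbours — is the common default for US county
models. Contact detection matches ring vertices after rounding coordinates
to 7 decimals (≈ 1 cm in degrees), exact for topologically clean layers;
boundaries touching only along the interior of an edge with no shared
vertex are missed, a known limitation relative to full
segment-intersection tests. Disconnected graphs are supported (one
sum-to-zero constraint per component); islands are reported and pinned at
$u_i = 0$.

## The Georgia example

The package bundles a transcription of published characteristics of the
159 Georgia counties with prostate cancer incidence, 2012-2016: nine
socio-demographic covariates, mean annual case counts, male populations and
crude rates per 100,000. `load_county_table("georgia_2012_2016")` returns
it with the modelled count reconstructed as `round(cases * 5)` (the table
prints mean *annual* cases over a 5-year window; `period_years` is
configurable). Two counties (Ben Hill, Jeff Davis) lack four covariate
columns; the fitting default mean-imputes them, preserving $n = 159$.
Income is summarized by the cross-county mean of the county-median incomes,
which is how the source table's summary row is computed.

County contiguity for Georgia is *not* bundled (it requires a county
polygon file). `run_pipeline()` derives queen contiguity when the user
supplies a GeoJSON; without geometry, `ring_graph()` offers a clearly
labelled synthetic stand-in adjacency so that the full spatial pipeline
remains runnable — results under it are a sensitivity exercise, not
geography. Under that stand-in, the Georgia analysis reproduces the broad
published pattern (county-mean relative risk near 1.2, the same handful of
small high-rate counties at the top, an age-structure effect that stays
significant in the spatial model); exact per-county values depend on the
true adjacency, the construction of $E_i$, covariate coding and priors,
none of which the source analysis pins down.

## Worked example

```{r example, eval = FALSE}
ga <- load_county_table("georgia_2012_2016") |>
  compute_expected_counts() |>
  add_smr()

fit <- fit_bym(ga, graph = ring_graph(ga$area_id, 2),
               covariates = county_covariates(),
               control = mcmc_control(seed = 1))
gelman_rubin(fit)
tidy(fit)
risk <- summarize_relative_risk(fit)
rank_areas(risk, "exceedance@2")
autoplot(fit)
```

## Limitations and non-goals

Only binary queen/rook-style adjacency is supported (no distance-band or
k-nearest weights). The proper-CAR, Leroux and BYM2 reparameterizations are
not implemented; BYM2's scaled, interpretable variance split is the natural
future extension. Model comparison criteria (DIC/WAIC) are not computed.
Expected counts are internally standardized only — external/age-adjusted
reference rates must be supplied by the user through the `expected`
column.
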