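---
title: "Trade-embodied NH3, PM2.5 mortality, and mitigation scenarios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trade-embodied NH3, PM2.5 mortality, and mitigation scenarios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nh3trade)
```

This vignette records how the package models each link of the chain from
agricultural ammonia emissions to trade-attributed premature mortality and
mitigation scenarios, which assumptions and parameter choices matter, and
where the genuinely open design decisions fell.

## The accounting model

A multiregional input–output (MRIO) table for $n$ economies with $k_s$
sectors each ($N = \sum_s k_s$) satisfies $X = AX + F$ with gross output
$X$, technical coefficients $A = Z\hat{X}^{-1}$ and final demand $F$. The
Leontief inverse $L = (I-A)^{-1}$ exists whenever the spectral radius of
$A$ is below one, which the generator guarantees by keeping every column's
intermediate-input share below 0.55. Sectoral NH$_3$ emission intensities
$D_i$ (Gg per monetary unit; zero outside crop and livestock sectors, one
intensity per category within a region) yield the embodied flow matrix
$C = \hat{D} L \hat{F}$ and its country aggregation $T_{st}$, the NH$_3$
emitted in economy $s$ embodied in the final consumption of economy $t$.

Two interpretation points were open and are resolved as follows:

* $\hat F$ is *destination-resolved*: the generator stores final demand as
  an $N \times n$ matrix (producing sector by consuming region), so $C$ is
  computed as $\hat D L F$ with columns indexed by consuming region. Any
  $N \times N$ block layout that aggregates to the same $T_{st}$ is
  equivalent; the destination-resolved form avoids inventing an allocation
  of a destination's demand across its own sector columns.
* Zero-output sectors get a zero coefficient column and zero intensity,
  with a warning, so degenerate toy tables never break the inversion. The
  solve uses LU factorization of $I - A$.

From $T$: $\mathrm{EEE}_s = \sum_{t \ne s} T_{st}$,
$\mathrm{EEI}_s = \sum_{t \ne s} T_{ts}$,
$\mathrm{EEB} = \mathrm{EEI} - \mathrm{EEE}$,
$\mathrm{PBE}_s = \sum_t T_{st}$, $\mathrm{CBE}_s = \sum_t T_{ts}$. The
identities $\sum_s \mathrm{EEB}_s = 0$, $\sum_{st} T_{st} = $ total
agricultural emissions, and crop/livestock additivity are enforced by
property tests on randomly generated balanced worlds.

## The synthetic world

The generator is the package's stand-in for the global input data and
defines the study conditions; its defaults are fixed once and are not
tuning knobs.

* **Economy.** Regional sizes are Pareto-like heavy-tailed so a few hub
  economies dominate, as in real trade networks. Region pairs trade with
  probability `trade_density` (0.7 default; symmetric existence,
  asymmetric heavy-tailed magnitudes). The transaction matrix is balanced
  by iterative proportional fitting against intermediate-use margins
  (row shares capped at 0.9, column shares drawn in 0.25–0.55, cap 20 000
  iterations, tolerance $10^{-10}$; margins are made consistent within
  each region so the autarkic `trade_density = 0` case also converges).
  Final demand is the exact row residual, so $X = Z\mathbf{1} +
  F\mathbf{1}$ holds to machine precision, with a 0.55–0.85 home-bias
  share of each sector's final sales.
* **Emissions.** One crop and one livestock intensity per region,
  log-normally dispersed across regions (σ = 0.5 by default) around
  0.004 and 0.009 Gg per monetary unit — livestock more
  emission-intensive per unit output, matching the sectoral ordering in
  global inventories. `perturb_inventory()` applies independent
  log-uniform factors in $[1/b, b]$; the default bound $b = 2.5$ sits in
  the factor-2–3 range reported for NH$_3$ inventory uncertainty.
* **Grids.** Regular cell-center-registered lat/lon grids over a toy
  domain (40° × 50°), coarse 2° × 2.5° like a global transport model and
  fine 0.5° by default (0.1° allowed, at desk-scale cost). Regions are
  contiguous longitude bands; population concentrates in three city cells
  per region (90 %) plus a uniform rural floor, summing to the configured
  world total (10⁹). Baseline mortality rates for ischemic heart disease,
  COPD, stroke and lung cancer are log-normal draws around
  1.5, 0.5, 1.1 and 0.3 per 1000 person-years — the order of magnitude of
  global cause-specific rates.
* **Dispersion surrogate.** Chemical-transport sensitivity runs are
  replaced by a strictly linear operator: an isotropic Gaussian kernel
  (scale 3°, planar degree distance) normalized per source cell so emitted
  mass is redistributed, not created, times a source–receptor strength of
  5 µg m⁻³ per Gg per cell. This preserves exactly the properties the
  attribution arithmetic relies on — linearity, near-source dominance,
  monotone decay — and nothing else of atmospheric chemistry. National
  emissions are allocated uniformly over a region's coarse mask cells,
  since no spatial proxy is part of the model.

What the generator does *not* emulate: real geography and transport
(advection, chemistry, seasonality), within-country heterogeneity of
emission intensities, demographic structure, and the sectoral detail of
real MRIO tables. Passing tests therefore demonstrate the correctness of
the accounting, attribution, network and optimization machinery under the
assumed structure, not the realism of any particular number.

## Exposure and mortality

Fractional contributions $(C_{tot} - C_{pert})/C_{tot}$ are computed on
the coarse grid, clipped to $[0,1]$ (clipping is logged; under the linear
surrogate it never triggers), and downscaled block-constant to the fine
grid — each fine cell inherits the coarse cell containing its center.
Relative risk follows the integrated exposure–response form
$RR(C) = 1 + \alpha(1 - e^{-\gamma (C - C_0)^{\delta}})$ for $C > C_0$,
continuous at $C_0$, bounded by $1 + \alpha$. The shipped central
parameters are synthetic values of plausible magnitude (the published
parameter tables are not redistributed); real tables can be supplied in
the same four-column layout. The counterfactual is drawn uniformly in
5.8–8.8 µg m⁻³ in the 1000-member ensemble; shape parameters get 20 %
log-normal dispersion. The headline mortality is the ensemble *mean of
mortality* (not mortality at mean parameters), with empirical 2.5/97.5
percentiles; a fixed seed makes the ensemble, and hence the mean,
bit-reproducible.

Attributable deaths are $y_0 \cdot \mathrm{pop} \cdot (1 - 1/RR)$ per cell
and cause; each cell belongs wholly to the region of its mask code.
Source attribution multiplies the total by the source's fractional
contribution, one perturbation run per (economy, sector); by linearity the
crop and livestock attributions sum exactly to the all-agriculture
attribution, which the suite asserts at $10^{-6}$ relative.

## The health-effect network

Bilateral flows $q_{ij} = \text{deaths}_i \cdot T_{ij}/\mathrm{EEE}_i$
(for $j \ne i$) distribute each economy's export-related deaths over its
consuming partners; the exact decomposition rule is the package's stated
interpretation, chosen so rows reproduce the per-economy totals exactly.
Statistics follow the weighted-network conventions: strengths are
threshold-independent row/column sums; the edge-existence threshold for
binary statistics defaults to 0 (any positive flow) and is configurable.

Betweenness sums over *ordered* pairs with endpoints excluded (so values
are twice the unordered convention); the weighted variant uses edge length
$1/w_{ij}$ on the symmetrized weights $w = q + q^{\top}$, so larger health
flows mean shorter paths — the natural reading of path length "defined by
the bilateral flows", surfaced as a configuration choice. Eigenvector
centrality is the principal eigenpair of the binary symmetrized adjacency
via shifted power iteration ($A + I$, immune to bipartite oscillation,
residual $10^{-10}$). Modularity is evaluated as the full double sum including the diagonal
null-model terms (with $w_{ii} = 0$). Community
detection is divisive Girvan–Newman — repeatedly remove the edge of
highest weighted betweenness, lexicographic tie-break, return the
dendrogram cut maximizing $Q$ — kept deterministic end to end; exhaustive
partition search provides the oracle at small $n$. On a dense toy network
of six economies the best cut is usually the whole graph (every pair
trades directly); the planted-block tests show the detector resolves
genuine bridge-separated structure, which is the regime the full-scale
network with its hundreds of sparse edges occupies. The degree fit is a
discrete maximum-likelihood power law with zeta-function normalization,
$k_{\min} = 1$ by default.

## Scenario programs

Climate compatibility uses closed intervals: $|\Delta AVT| \le 5$ °C and
$|\Delta PCP| \le 500$ mm. Import substitution maximizes
$\sum_j (EI_j - EI_i)\,ST_{ij}$ per importer independently (as the problem
is indexed), subject to capacity $\sum_j ST_{ij} \le AC_i$ and flow bounds
$0 \le ST_{ij} \le IM_{ij}$ over climate-compatible partners. Export
transfer *minimizes* $\sum_i EX^{AF}_i EI_i$ — the scenario exists to
reduce trade-related emissions, so minimization is the only coherent
objective direction — subject to exact conservation of total exports,
capacity $EX^{AF}_i \le AC_i + EX^0_i$, and the aggregate
compatible-coverage constraint $EX^0_i \le \sum_j I_{ij} EX^{AF}_j$,
kept in its aggregate form (it does not track which country replaces
which flow). The original export vector is always
feasible, so reductions are non-negative by construction. Both programs
are solved with the simplex method with a fixed variable ordering; the
reported solution includes the active-constraint set so alternative optima
are detectable, and both are verified against exhaustive vertex
enumeration on all 2–3-region test problems to an objective gap of
$10^{-7}$.

Technology scenarios apply fixed literature rates: 14 % of crop NH$_3$
(removing fertilizer overuse), 55 % and 54 % of grain-crop NH$_3$ (deep
placement, enhanced-efficiency fertilizers — scaled by a configurable
grain share of crop NH$_3$, default 1 on synthetic data where no external
grain split exists), 35 % and 70 % of livestock NH$_3$ (moderate/drastic
manure management). Food-waste elimination removes
$\text{crop} \times r_{crop} + \text{livestock} \times r_{meat}$ per
country; beef substitution removes
$\text{livestock} \times \text{beef share} \times \text{cut}$, linear in
the cut with the added soy emissions taken as negligible. Health
re-evaluation applies each region's reduction as a uniform within-country
scaling of gridded NH$_3$, reruns the surrogate and the IER chain with
population and baseline mortality fixed, and reports avoided deaths.

## Numerical choices and problem sizes

Balance is asserted at $10^{-9}$ relative; conservation identities at
$10^{-8}$; the Leontief-vs-Neumann oracle at $10^{-8}$; eigen-residuals at
$10^{-8}$; LP oracles at $10^{-7}$; attribution additivity at $10^{-6}$.
The tests and the acceptance script run worlds of 2–6 regions on the 0.5°
fine grid (8 000 cells), 50-world property sweeps for the accounting
identities, exhaustive network oracles up to $n = 8$ nodes (Bell-number
partition enumeration), 2 000 simulated degrees for the power-law
recovery, and the full 1000-member ensemble where uncertainty is the
point — sizes chosen so the whole suite completes in well under a minute
while every contract is exercised at full tolerance.

## Known limitations

* The dispersion surrogate is linear by design; real PM$_2.5$ chemistry is
  not, and the uniform-over-mask emission allocation ignores spatial
  proxies. Fractional contributions on real data would need
  transport-model sensitivity runs.
* IER central parameters are synthetic; absolute mortality levels from the
  toy world are not interpretable, only the structure of the chain.
* The aggregation-error correction for coarse sector classifications is a
  data-dependent manual step and is not implemented; a hook accepts an
  externally supplied export re-weighting vector.
* Import substitution is solved per importer and export transfer per
  community; joint general-equilibrium effects (prices, demand responses)
  are out of scope, as is any multi-year dynamics.
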