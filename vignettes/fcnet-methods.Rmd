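---
title: "Methods: connectivity networks, graph metrics, and group inference in fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity networks, graph metrics, and group inference in fcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fcnet implements a data-driven resting-state functional-connectivity
analysis over parcellated brain signals: Pearson correlation networks at a
fixed edge density, small-world and modularity measures against random
benchmarks, Euclidean connection-reach statistics, hub and seed-region
profiles, and group inference by pooled t-tests, label-permutation tests
with false-discovery-rate control, and pooled two-proportion z-tests.
Because no subject-level recordings are distributable with the package, a
calibrated synthetic cohort generator stands in for real data; this
vignette describes the model, the analysis chain, the numerical
conventions, and the choices made where the design was genuinely open.

## The synthetic cohort model

Each subject is a matrix of `n_nodes` regional signals over `n_volumes`
time points. Node $i$'s series is a latent-factor mixture

$$x_i(t) = g\, s(t) + w\, u_{m(i)}(t) + b\, \rho_i\, v(t) + \sigma_\epsilon\, \epsilon_i(t),$$

where $s$ is a global fluctuation shared by all nodes, $u_c$ is one
fluctuation per bilateral module, $v$ is a long-range fluctuation shared by
the flagged node subset ($\rho_i \in \{0,1\}$), and $\epsilon_i$ is
node-specific noise. All innovations are mutually independent, AR(1)
smoothed (coefficient `temporal_smoothing`), and re-standardized to unit
variance, so for two distinct nodes the model-implied correlation has the
closed form implemented in `expected_correlation()`:

$$r_{ij} = \frac{g^2 + w^2\,[m(i){=}m(j)] + b^2 \rho_i \rho_j}
{\sqrt{(g^2+w^2+b^2\rho_i+\sigma_\epsilon^2)(g^2+w^2+b^2\rho_j+\sigma_\epsilon^2)}}.$$

Tests verify this oracle against long-run Monte-Carlo simulation
($T = 10^5$) to within $\pm 0.01$ absolute.

Geometry: nodes come in mirrored left/right pairs; bilateral module centers
are placed at mutually distinct positions in a $\pm 70$ mm box and node
centroids add isotropic 8 mm jitter, mirrored in $x$. With the default 55
pairs per hemisphere, 48 carry cortical placeholder names and 7 carry the
standard subcortical names (thalamus, caudate, putamen, pallidum, amygdala,
accumbens, hippocampus), giving the 110-region bilateral parcellation the
analysis assumes and a natural right-caudate seed node.

### Defaults and calibration

The default configuration encodes the emulated study conditions: 16
controls vs 14 cases, 110 nodes in 8 modules, 128 volumes. The two group
effects are:

* **Global coupling** `global_coupling_control = 0.3`,
  `global_coupling_case = 0.45`. Cases couple more strongly to the shared
  signal, raising their mean pairwise correlation. The values were chosen
  once so that the case offset in the raw grand mean is reliably detectable
  at these group sizes while leaving thresholded-network topology largely
  intact, which is the qualitative pattern the analysis is designed to
  resolve (a connectivity-strength offset without gross small-world
  reorganization).
* **Long-range coupling** `longrange_coupling_control = 0.3`,
  `longrange_coupling_case = 0.9` at `longrange_node_fraction = 0.15` of
  nodes (16 of 110). Flagged pairs are spread round-robin over a
  greedily chosen max-min-separated set of modules, so when $b$ rises each
  flagged node gains several spatially distant partners among its retained
  top-20% correlations and its mean neighbor Euclidean distance grows. The
  fraction matches the scale of node-level effects the analysis should
  detect (tens of regions, not one or all).

`module_coupling = 0.8` and `noise_sd = 1` put within-module correlations
near 0.4 and cross-module correlations near 0.05–0.1 before removal, so
proportional thresholding at 20% keeps all within-module structure plus a
tail of cross-module edges — networks that are modular, connected, and
small-world ($\sigma \approx 2.5$), in the regime the measures assume.
`temporal_smoothing = 0.3` adds mild temporal autocorrelation emulating
slow fluctuations; since Pearson correlation at fixed $T$ is the only
consumer, white noise (0) is equally valid and supported.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis relies on: two groups,
modular correlation structure, a group offset in global correlation, and
node-specific long-range coupling tied to real geometry. It does **not**
simulate hemodynamics, band-limited spectra, motion or physiological
artifacts, volumetric images, or spatially heterogeneous noise. Passing
tests therefore demonstrate that the pipeline recovers known effects from
data with this covariance structure — not that it is robust to fMRI
preprocessing pathologies, which are out of scope.

## The analysis chain

Per subject: **demean** each row; **remove the global signal** (subtract
the across-node mean time course); **correlate** (Pearson, diagonal stored
as 1 but excluded from every summary); derive the **non-negative** variant
(negatives zeroed) and the **thresholded binary network**. Proportional
thresholding ranks the $n(n-1)/2$ upper-triangle correlations and keeps the
top $\lfloor \text{density} \cdot n(n-1)/2 \rfloor$ pairs as edges — at the
default 20% on 110 nodes, exactly 1,199 of 5,995 pairs for every subject,
which is what makes topology comparable across subjects. Grand means
average the upper triangle only; the thresholded grand mean averages
retained correlations only (the alternative — zeros included — would scale
it by the density and is recoverable from the reported values).

Graph measures on the binary network: degree $k_i$; local clustering $C_i$
(0 when $k_i < 2$) and its mean $C$; characteristic path length $L$ over
reachable ordered pairs (breadth-first); a random benchmark of uniform
$G(n,m)$ graphs with matched node and edge counts (mean $L_r$, $C_r$ over
100 realizations); $\gamma = C/C_r$, $\lambda = L/L_r$, and small-worldness
$\sigma = \gamma/\lambda = C L_r / (C_r L)$; and Newman modularity $Q$
maximized by the seeded Louvain heuristic. The $Q$ evaluation of a given
partition is exposed separately (`modularity_value()`) and is checked
against an exhaustive-partition oracle on small graphs.

Spatial and local analyses: the Euclidean distance between centroids of
connected nodes approximates connection reach; each node's mean distance to
its neighbors is the node-level reach statistic (undefined for isolated
nodes). Hubs are the top 15 nodes by degree; hub frequency is the fraction
of a group's subjects in which a node makes the top set. The seed profile
counts, per node, the subjects of each group connected to the seed;
group-specific partners are present in one group and absent in the other,
and shared partners are tested with the pooled two-proportion z
($|z| > 2$).

Inference: global measures use the pooled-variance two-sample t at
$\alpha = 0.05$, plus the within-group Pearson test of $C$ against $Q$
($t$ on $n-2$ df). Node-wise measures use label permutations — the same
relabeling applied to every node, pooled t as statistic, two-sided add-one
p-value $(1 + \#\{|t^\ast| \ge |t|\})/(B+1)$ with $B = 5000$ by default —
followed by Benjamini–Hochberg FDR at 5% within each metric family (110
tests per family). The per-node permutation p-values are reported, so an
uncorrected $p < 0.01$ reading remains available from the output tables
without rerunning.

## Numerical conventions and edge cases

* **Tie-breaking.** Correlation ties at the threshold cutoff and degree
  ties in hub ranking resolve by node-index order: deterministic, and
  irrelevant on continuous data where ties have measure zero.
* **Rounding.** Edge count is the floor of density × pairs, guaranteeing
  realized density ≤ requested. Only strictly positive correlations are
  eligible; if fewer exist than requested, all positives are kept and a
  warning is recorded.
* **Disconnection.** $L$ averages reachable pairs only, with a warning
  stating how many ordered pairs were excluded; an isolated node has
  undefined $L_i$ (and undefined mean neighbor distance). In node-wise
  comparisons, undefined values are imputed with the node's cross-subject
  mean so permutations stay balanced; at 20% density on these data networks
  are connected and the imputation never fires.
* **Degenerate statistics.** A node constant across all subjects gets
  $t = 0$ (hence $p = 1$); zero pooled variance with unequal means gives
  $t = \pm\infty$, which the permutation comparison handles by equality of
  magnitude. The pooled z is flagged undefined when the pooled frequency is
  0 or 1. Pearson $|r| = 1$ returns $p = 0$ with a degeneracy flag.
* **Determinism.** Every stochastic stage (subject simulation, benchmark
  graphs, Louvain, permutations) takes a seed derived from one master seed
  by a fixed offset scheme, so end-to-end runs are bit-reproducible and
  stages can be re-run in isolation. Series and centroids are written to
  text with 17 significant digits so cohorts round-trip losslessly.

## Open design points and how they were resolved

* **$\gamma$ and $\lambda$.** The package defines $\gamma$ as the
  clustering ratio $C/C_r$ and $\lambda$ as the path-length ratio $L/L_r$,
  the convention under which $\gamma \gg 1$, $\lambda \approx 1$ for
  small-world networks and $\sigma = \gamma/\lambda$; field usage of the
  two symbols is not fully consistent, and the magnitudes disambiguate.
* **Benchmark model.** Uniform $G(n,m)$ with matched nodes and edges, 100
  realizations, rather than degree-preserving rewiring — the weakest
  benchmark consistent with "same number of nodes and edges", and the one
  whose clustering approaches the edge density analytically (a property the
  tests check).
* **Node-wise $\sigma_i$** is defined as $C_i L_r / (C_r L_i)$ against the
  network-level benchmark: a node-local analog of the global formula. It is
  reported alongside $k$, $C_i$, $L_i$ for completeness.
* **Global-signal removal and the global coupling effect.** Removal
  subtracts the across-node mean, after which the residuals sum to zero at
  every time point; consequently the sum of off-diagonal residual
  covariances equals minus the sum of residual variances, and a factor
  loaded equally on all nodes — the generator's $g\,s(t)$ term — is
  annihilated exactly. The group offset in global coupling is therefore
  assessed on correlation matrices computed before removal, and the
  pipeline records the pre-removal grand mean (`grand_mean_preremoval`)
  alongside the post-removal battery. On real recordings, heterogeneous
  loadings and non-stationarities leave residual global differences that
  this idealized model cannot, which is a known limitation.
* **Seed-profile attribution.** A connection is attributed to a group if at
  least one subject shows it (threshold $1/n_\text{group}$), the weakest
  reading of "specific"; stricter consensus thresholds are a function
  argument. Hub-frequency denominators are full group sizes.

## Problem sizes

The shipped test-suite and workflow sizes are chosen to keep everything
desk-scale while preserving the study conditions where they matter: the
structural, thresholding, directional-recovery and reproducibility checks
run at the full 110-node, 30-subject configuration; the null
error-control simulation uses 100 cohort replicates at 1,000 permutations
(the acceptance script) and 60 replicates at 500 permutations (the test
suite); mechanical unit tests use 20-node cohorts and toy graphs where the
property under test does not depend on scale.

## Known limitations

Pearson correlation only (no partial correlations or spectral variants);
binary undirected networks at a single density; no weighted metrics,
efficiency, or betweenness; no covariate adjustment in the inference; the
generator's idealizations listed above. These bounds are deliberate: they
delimit the claims the package makes.
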